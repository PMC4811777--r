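#' Expression z-scores against a reference (control) distribution
#'
#' Standardizes one gene's per-sample expression against the mean and
#' unbiased standard deviation of a designated reference subset:
#' `z = (x - mean(ref)) / sd(ref)`.
#'
#' @param values named numeric vector: one gene's expression per sample.
#' @param reference_ids sample ids defining the control distribution; at
#'   least two, with nonzero spread.
#' @return named numeric vector of z-scores for all samples.
#' @export
compute_zscores <- function(values, reference_ids) {
  if (!is.numeric(values) || is.null(names(values)))
    stop("'values' must be a named numeric vector")
  missing <- setdiff(reference_ids, names(values))
  if (length(missing))
    stop("reference sample(s) absent: ", paste(missing, collapse = ", "))
  if (length(reference_ids) < 2L)
    stop("need at least 2 reference samples")
  ref <- values[reference_ids]
  s <- stats::sd(ref)
  if (s == 0) stop("reference samples have zero spread")
  (values - mean(ref)) / s
}

#' Two-sided Wilcoxon / Mann-Whitney rank-sum test
#'
#' Compares two independent groups of z-scores. The exact null distribution
#' is enumerated when the combined sample size is at most `exact_cutoff` and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used (mid-ranks for ties).
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @param exact_cutoff combined-size cutoff for the exact test (default 12).
#' @return object of class `cohort_test`: list with `statistic` (Mann-Whitney
#'   U of `group_a`), `p_value`, `method` (`"rank-sum exact"` or
#'   `"rank-sum normal-approx"`), `n_a`, `n_b`.
#' @export
rank_sum_test <- function(group_a, group_b, exact_cutoff = 12) {
  if (length(group_a) < 1L || length(group_b) < 1L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && (length(group_a) + length(group_b)) <= exact_cutoff
  if (max(c(group_a, group_b)) == min(c(group_a, group_b))) {
    # fully tied data: no evidence against the null under mid-ranks
    return(structure(list(statistic = length(group_a) * length(group_b) / 2,
                          p_value = 1, method = "rank-sum normal-approx",
                          n_a = length(group_a), n_b = length(group_b)),
                     class = "cohort_test"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = min(wt$p.value, 1),
                 method = if (exact) "rank-sum exact" else
                   "rank-sum normal-approx",
                 n_a = length(group_a), n_b = length(group_b)),
            class = "cohort_test")
}

#' Rank-sum contrast between cohort groups
#'
#' Splits a cohort table into two groups — by mutation status, or by a
#' two-cell partition of subtype labels (e.g. GCiMP + Proneural versus
#' Neural + Classical + Mesenchymal) — and runs [rank_sum_test()] on the
#' z-scores, reporting group sizes and medians.
#'
#' @param table cohort data frame with columns `sample_id`, `zscore`, and
#'   `mutation_status` and/or `subtype`.
#' @param grouping either the string `"mutation_status"` (mutant vs
#'   wild-type) or a list of two character vectors of subtype labels, e.g.
#'   `list(a = c("GCiMP", "Proneural"), b = c("Neural", "Classical",
#'   "Mesenchymal"))`.
#' @param exact_cutoff passed to [rank_sum_test()].
#' @return `cohort_test` with an added `groups` data frame (label, n,
#'   median).
#' @export
group_contrast <- function(table, grouping = "mutation_status",
                           exact_cutoff = 12) {
  if (!is.data.frame(table) || !all(c("sample_id", "zscore") %in% names(table)))
    stop("'table' needs columns 'sample_id' and 'zscore'")
  if (identical(grouping, "mutation_status")) {
    if (!"mutation_status" %in% names(table))
      stop("'table' has no 'mutation_status' column")
    a <- table$zscore[table$mutation_status == "mutant"]
    b <- table$zscore[table$mutation_status == "wild-type"]
    labels <- c("mutant", "wild-type")
  } else if (is.list(grouping) && length(grouping) == 2L) {
    if (!"subtype" %in% names(table))
      stop("'table' has no 'subtype' column")
    valid <- unique(table$subtype)
    unknown <- setdiff(unlist(grouping), valid)
    if (length(unknown))
      stop("unknown subtype label(s): ", paste(unknown, collapse = ", "),
           "; valid: ", paste(valid, collapse = ", "))
    a <- table$zscore[table$subtype %in% grouping[[1L]]]
    b <- table$zscore[table$subtype %in% grouping[[2L]]]
    labels <- vapply(grouping, paste, "", collapse = "+")
  } else {
    stop("'grouping' must be \"mutation_status\" or a list of two label sets")
  }
  if (length(a) == 0L || length(b) == 0L)
    stop("both partition cells must be non-empty")
  res <- rank_sum_test(a, b, exact_cutoff = exact_cutoff)
  res$groups <- data.frame(label = labels,
                           n = c(length(a), length(b)),
                           median = c(stats::median(a), stats::median(b)),
                           stringsAsFactors = FALSE)
  res
}

#' Cross-platform z-score concordance (Spearman)
#'
#' Spearman rank correlation of two cohort tables' z-scores over the samples
#' present in both (mid-ranks for ties). Used to check that two measurement
#' platforms (e.g. microarray and RNA-seq) agree.
#'
#' @param table_a,table_b cohort data frames with `sample_id` and `zscore`.
#' @return `cohort_test` with `statistic` = Spearman rho, `p_value` from the
#'   asymptotic test, `method = "spearman"`, and `n_overlap`.
#' @export
platform_concordance <- function(table_a, table_b) {
  for (t in list(table_a, table_b))
    if (!is.data.frame(t) || !all(c("sample_id", "zscore") %in% names(t)))
      stop("cohort tables need columns 'sample_id' and 'zscore'")
  shared <- intersect(table_a$sample_id, table_b$sample_id)
  if (length(shared) < 3L)
    stop("need at least 3 overlapping samples (found ", length(shared), ")")
  za <- table_a$zscore[match(shared, table_a$sample_id)]
  zb <- table_b$zscore[match(shared, table_b$sample_id)]
  rho <- stats::cor(za, zb, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(za, zb, method = "spearman", exact = FALSE)$p.value)
  structure(list(statistic = rho, p_value = p, method = "spearman",
                 n_overlap = length(shared)),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  if (!is.null(x$groups)) print(x$groups, row.names = FALSE)
  invisible(x)
}
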