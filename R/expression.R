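#' Generalized-log (variance-stabilizing) transform
#'
#' Maps raw positive intensities to a log2-like scale using the glog transform
#' `log2((x + sqrt(x^2 + c^2)) / 2)`. With `glog_c = 0` this is plain `log2`;
#' a positive constant damps the variance inflation of low intensities, the
#' usual variance-stabilization intent for bead-array data. The transform is
#' strictly monotone, so within-sample rankings are preserved.
#'
#' @param x numeric matrix of raw intensities, genes in rows, samples in
#'   columns. All values must be strictly positive and finite.
#' @param glog_c non-negative glog constant, on the raw intensity scale.
#'   Default 0 (plain log2).
#' @return numeric matrix of the same shape on the log2 scale.
#' @export
#' @examples
#' m <- matrix(c(8, 2, 4, 16), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' glog_transform(m)        # log2
#' glog_transform(m, 10)    # damped at low intensity
glog_transform <- function(x, glog_c = 0) {
  x <- as_expr_matrix(x)
  if (!is.numeric(glog_c) || length(glog_c) != 1L || is.na(glog_c) || glog_c < 0)
    stop("'glog_c' must be a single non-negative number")
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    stop(sprintf(
      "raw intensities must be positive and finite; offending value %s at gene '%s', sample '%s'",
      format(x[bad[1L]]), rownames(x)[i[1L]], colnames(x)[i[2L]]))
  }
  out <- log2((x + sqrt(x^2 + glog_c^2)) / 2)
  dimnames(out) <- dimnames(x)
  out
}

#' Quantile normalization
#'
#' Forces every sample (column) to share one empirical distribution: each
#' value is replaced by the across-sample mean of same-rank values. Ties
#' within a sample receive the mean of the reference values their ranks span,
#' so tied inputs stay tied. The operation is idempotent and leaves a matrix
#' of identical columns unchanged.
#'
#' @param x numeric matrix on the log2 scale, genes in rows, at least two
#'   sample columns, no missing values.
#' @return matrix of the same shape; every column is a permutation of the
#'   shared reference distribution (up to tie averaging).
#' @export
quantile_normalize <- function(x) {
  x <- as_expr_matrix(x)
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least 2 samples")
  if (anyNA(x)) stop("missing values are not supported")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    res <- numeric(length(v))
    res[order(v)] <- ref
    # tie groups (exact value equality) get the mean of the spanned refs
    out[, j] <- stats::ave(res, match(v, v), FUN = mean)
  }
  out
}

#' Collapse technical duplicates
#'
#' Averages technical-duplicate columns into one column per replicate group
#' and reports the Pearson correlation of every within-group pair as a QC
#' check. Pairs below `min_corr` are flagged with a warning (or an error in
#' strict mode); they are never silently dropped, mirroring the usual
#' bead-array QC convention that high duplicate correlation is verified, not
#' filtered on.
#'
#' @param x numeric log2 expression matrix, one column per array.
#' @param annotation data frame with columns `sample_id`, `condition`,
#'   `replicate_group`; every matrix column must be annotated and a replicate
#'   group must not span two conditions.
#' @param min_corr QC floor for duplicate Pearson correlation (default 0.996).
#' @param strict if `TRUE`, a pair below `min_corr` is an error instead of a
#'   warning.
#' @return list with `values` (matrix, one column per replicate group, in
#'   first-appearance order), `annotation` (collapsed: `sample_id`,
#'   `condition`), and `correlations` (data frame of within-group pairs with
#'   columns `replicate_group`, `sample_a`, `sample_b`, `correlation`,
#'   `flagged`).
#' @export
collapse_duplicates <- function(x, annotation, min_corr = 0.996, strict = FALSE) {
  x <- as_expr_matrix(x)
  annotation <- check_annotation(annotation, colnames(x))
  split_cond <- tapply(annotation$condition, annotation$replicate_group,
                       function(v) length(unique(v)))
  if (any(split_cond > 1L))
    stop("replicate group(s) spanning multiple conditions: ",
         paste(names(split_cond)[split_cond > 1L], collapse = ", "))

  groups <- unique(annotation$replicate_group)
  out <- matrix(NA_real_, nrow(x), length(groups),
                dimnames = list(rownames(x), groups))
  pairs <- list()
  for (g in groups) {
    ids <- annotation$sample_id[annotation$replicate_group == g]
    out[, g] <- rowMeans(x[, ids, drop = FALSE])
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      for (k in seq_len(ncol(cmb))) {
        r <- stats::cor(x[, cmb[1L, k]], x[, cmb[2L, k]])
        pairs[[length(pairs) + 1L]] <- data.frame(
          replicate_group = g, sample_a = cmb[1L, k], sample_b = cmb[2L, k],
          correlation = r, flagged = r < min_corr,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(replicate_group = character(), sample_a = character(),
               sample_b = character(), correlation = numeric(),
               flagged = logical(), stringsAsFactors = FALSE)
  if (any(report$flagged)) {
    msg <- sprintf("%d duplicate pair(s) below the %.3f correlation floor (min observed %.4f)",
                   sum(report$flagged), min_corr, min(report$correlation))
    if (strict) stop(msg) else warning(msg)
  }
  cond <- annotation$condition[match(groups, annotation$replicate_group)]
  list(values = out,
       annotation = data.frame(sample_id = groups, condition = cond,
                               stringsAsFactors = FALSE),
       correlations = report)
}

#' Mean log2 fold-change profile of a condition against the reference
#'
#' Per gene, the mean log2 expression of the condition samples minus the mean
#' of the reference samples, computed on a collapsed (one column per
#' biological sample) matrix.
#'
#' @param x collapsed log2 expression matrix.
#' @param annotation data frame with `sample_id` and `condition` covering the
#'   matrix columns.
#' @param condition condition label to profile; must differ from `reference`.
#' @param reference reference condition label (default `"wt"`).
#' @return named numeric vector of log2 fold changes (one per gene, in matrix
#'   row order) with attributes `condition` and `reference`.
#' @export
fold_change_profile <- function(x, annotation, condition, reference = "wt") {
  x <- as_expr_matrix(x)
  annotation <- check_annotation(annotation, colnames(x), need_group = FALSE)
  known <- unique(annotation$condition)
  for (lbl in c(condition, reference))
    if (!lbl %in% known)
      stop(sprintf("unknown condition '%s'; available: %s", lbl,
                   paste(known, collapse = ", ")))
  if (identical(condition, reference))
    stop("'condition' must differ from 'reference'")
  cond_ids <- annotation$sample_id[annotation$condition == condition]
  ref_ids  <- annotation$sample_id[annotation$condition == reference]
  fc <- rowMeans(x[, cond_ids, drop = FALSE]) -
        rowMeans(x[, ref_ids, drop = FALSE])
  attr(fc, "condition") <- condition
  attr(fc, "reference") <- reference
  fc
}

#' Select deregulated genes at a fold threshold
#'
#' A gene is deregulated when its absolute log2 fold change strictly exceeds
#' `log2(fold_threshold)` ("more than" is strict). Direction is the sign of
#' the fold change.
#'
#' @param profile named numeric vector of log2 fold changes (see
#'   [fold_change_profile()]).
#' @param fold_threshold fold-change threshold on the linear scale, > 1
#'   (default 1.5).
#' @return data frame with columns `gene`, `direction` (`"up"`/`"down"`),
#'   `logfc_primary`, in input gene order, plus attributes `fold_threshold`
#'   and `counts` (named vector `up`/`down`).
#' @export
select_deregulated <- function(profile, fold_threshold = 1.5) {
  profile <- check_profile(profile)
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      fold_threshold <= 1)
    stop("'fold_threshold' must be a single number > 1")
  cut <- log2(fold_threshold)
  keep <- abs(profile) > cut
  out <- data.frame(
    gene = names(profile)[keep],
    direction = ifelse(profile[keep] > 0, "up", "down"),
    logfc_primary = unname(profile[keep]),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' Classify rescue of deregulated genes in a second comparison
#'
#' A deregulated gene is "rescued" when the second condition's fold change
#' against the same reference falls back inside the fold band, i.e.
#' `|logFC_secondary| <= log2(fold_threshold)` (non-strict: the complement of
#' the strict selection rule). Typical use: genes deregulated in a single
#' mutant that return to wild-type levels in a double mutant.
#'
#' @param dereg deregulated gene set from [select_deregulated()].
#' @param secondary_profile log2 fold-change profile of the second condition
#'   against the same reference; must cover every deregulated gene.
#' @param fold_threshold fold band for the rescue call; defaults to the
#'   threshold stored on `dereg`.
#' @return `dereg` with added columns `logfc_secondary` and `rescued`, and a
#'   `summary` attribute: list with per-direction rescued/total counts and
#'   fractions plus the overall fraction.
#' @export
classify_rescue <- function(dereg, secondary_profile,
                            fold_threshold = attr(dereg, "fold_threshold")) {
  secondary_profile <- check_profile(secondary_profile)
  if (is.null(fold_threshold)) fold_threshold <- 1.5
  missing <- setdiff(dereg$gene, names(secondary_profile))
  if (length(missing))
    stop("deregulated gene(s) missing from the secondary profile: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  out <- dereg
  out$logfc_secondary <- unname(secondary_profile[dereg$gene])
  out$rescued <- abs(out$logfc_secondary) <= log2(fold_threshold)
  n_up <- sum(out$direction == "up"); n_down <- sum(out$direction == "down")
  r_up <- sum(out$rescued & out$direction == "up")
  r_down <- sum(out$rescued & out$direction == "down")
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "summary") <- list(
    rescued_up = r_up, total_up = n_up,
    rescued_down = r_down, total_down = n_down,
    fraction_up = if (n_up) r_up / n_up else NA_real_,
    fraction_down = if (n_down) r_down / n_down else NA_real_,
    fraction_overall = if (nrow(out)) sum(out$rescued) / nrow(out) else NA_real_)
  out
}

# ---- internal helpers -------------------------------------------------------

as_expr_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("gene%04d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("sample%02d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  x
}

check_annotation <- function(annotation, sample_ids, need_group = TRUE) {
  req <- c("sample_id", "condition", if (need_group) "replicate_group")
  if (!is.data.frame(annotation) || !all(req %in% names(annotation)))
    stop("annotation must be a data frame with columns: ",
         paste(req, collapse = ", "))
  annotation <- annotation[match(sample_ids, annotation$sample_id), , drop = FALSE]
  if (anyNA(annotation$sample_id))
    stop("unannotated sample(s): ",
         paste(setdiff(sample_ids, annotation$sample_id), collapse = ", "))
  annotation
}

check_profile <- function(profile) {
  if (!is.numeric(profile) || is.null(names(profile)))
    stop("a fold-change profile must be a named numeric vector")
  if (anyNA(profile)) stop("fold-change profile contains missing values")
  profile
}
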