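#' Map a fold-change profile onto a centroid signature across species
#'
#' Translates profile gene symbols through a source-to-target symbol map
#' (e.g. mouse to human) and restricts the result to the signature genes of a
#' centroid set, in centroid row order. Duplicate source symbols in the map
#' are resolved before mapping; several profile genes landing on the same
#' signature gene are collapsed by the chosen policy.
#'
#' @param profile named numeric vector of log2 fold changes.
#' @param gene_map data frame with columns `source`, `target`. Duplicate
#'   `source` rows keep the first occurrence (with a warning).
#' @param centroids centroid matrix: signature genes in rows (rownames),
#'   subtypes in columns.
#' @param collapse how to combine several profile genes mapping to one
#'   signature gene: `"mean"` (default) or `"first"`.
#' @param min_fraction warn when fewer than this fraction of signature genes
#'   is mapped (default 0.5). Zero mapped genes is an error.
#' @return named numeric vector over the mapped signature genes, in centroid
#'   order, with attributes `n_mapped` and `n_signature`.
#' @export
map_profile <- function(profile, gene_map, centroids,
                        collapse = c("mean", "first"), min_fraction = 0.5) {
  profile <- check_profile(profile)
  collapse <- match.arg(collapse)
  centroids <- check_centroids(centroids)
  if (!is.data.frame(gene_map) || !all(c("source", "target") %in% names(gene_map)))
    stop("'gene_map' must be a data frame with columns 'source' and 'target'")
  if (nrow(gene_map) == 0L) stop("'gene_map' is empty")
  dup <- duplicated(gene_map$source)
  if (any(dup)) {
    warning(sum(dup), " duplicate source symbol(s) in gene map; keeping first")
    gene_map <- gene_map[!dup, , drop = FALSE]
  }
  gene_map <- gene_map[gene_map$source %in% names(profile), , drop = FALSE]
  signature <- rownames(centroids)
  gene_map <- gene_map[gene_map$target %in% signature, , drop = FALSE]
  if (nrow(gene_map) == 0L)
    stop("no profile gene maps onto the centroid signature")
  vals <- profile[gene_map$source]
  mapped <- if (collapse == "mean") {
    tapply(vals, gene_map$target, mean)
  } else {
    vals[!duplicated(gene_map$target)][
      order(match(unique(gene_map$target), signature))]
  }
  mapped <- setNames(as.numeric(mapped[signature[signature %in% names(mapped)]]),
                     signature[signature %in% names(mapped)])
  frac <- length(mapped) / length(signature)
  if (frac < min_fraction)
    warning(sprintf("only %d of %d signature genes mapped (%.0f%%)",
                    length(mapped), length(signature), 100 * frac))
  attr(mapped, "n_mapped") <- length(mapped)
  attr(mapped, "n_signature") <- length(signature)
  mapped
}

#' Distance of a profile to each subtype centroid
#'
#' Correlation distances are `1 - correlation` (range 0 to 2); small means
#' similar. Euclidean is the L2 norm of the difference.
#'
#' @param profile named numeric vector over signature genes (see
#'   [map_profile()]).
#' @param centroids centroid matrix (genes x subtypes); only the profile's
#'   genes are used.
#' @param metric `"spearman"` (default; robust to cross-platform scale),
#'   `"pearson"` or `"euclidean"`.
#' @return named numeric vector, one distance per subtype.
#' @export
centroid_distance <- function(profile, centroids,
                              metric = c("spearman", "pearson", "euclidean")) {
  metric <- match.arg(metric)
  profile <- check_profile(profile)
  centroids <- check_centroids(centroids)
  missing <- setdiff(names(profile), rownames(centroids))
  if (length(missing))
    stop("profile gene(s) absent from centroids: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  cm <- centroids[names(profile), , drop = FALSE]
  if (metric %in% c("spearman", "pearson")) {
    if (length(profile) < 3L)
      stop("correlation metrics need at least 3 shared genes")
    if (stats::sd(profile) == 0)
      stop("zero-variance profile under a correlation metric")
    csd <- apply(cm, 2L, stats::sd)
    if (any(csd == 0))
      stop("zero-variance centroid under a correlation metric: ",
           paste(colnames(cm)[csd == 0], collapse = ", "))
  }
  d <- switch(metric,
    spearman  = 1 - drop(stats::cor(rank(profile), apply(cm, 2L, rank))),
    pearson   = 1 - drop(stats::cor(profile, cm)),
    euclidean = sqrt(colSums((cm - profile)^2)))
  setNames(as.numeric(d), colnames(cm))
}

#' Bootstrap null distribution of centroid distances
#'
#' Builds a no-association null for the distances by resampling the profile's
#' fold-change values and reassigning them to signature positions *without*
#' preserving gene pairing (centroids stay fixed in their original gene
#' order). With pairing preserved the null would be centered on the observed
#' distance and could never show a low-distance tail; the unpaired scheme
#' gives a proper null of "these fold-change values, but no gene-level
#' association with the centroid". The default resamples with replacement
#' (bootstrap); a without-replacement permutation variant is available.
#'
#' When the bootstrap assignment space `n^n` is at most `enumerate_cap`, all
#' equally likely assignments are enumerated instead of sampled, giving the
#' exact null and expected distance.
#'
#' @param profile named numeric vector over signature genes.
#' @param centroids centroid matrix (genes x subtypes).
#' @param metric distance metric, as in [centroid_distance()].
#' @param B number of resamples (default 1000).
#' @param seed optional integer seed for reproducible resampling.
#' @param scheme `"bootstrap"` (with replacement, default) or
#'   `"permutation"` (without replacement).
#' @param enumerate `"auto"` (default: enumerate when feasible), `"never"`,
#'   or `"always"` (error if infeasible). Enumeration applies to the
#'   bootstrap scheme only.
#' @param enumerate_cap maximum number of enumerated assignments (default
#'   250000).
#' @return list with `null` (matrix, replicates x subtypes), `expected`
#'   (named vector of mean null distances), `B`, `scheme`, `exact` (logical:
#'   enumerated), and `n_redrawn` (constant resamples redrawn under a
#'   correlation metric).
#' @export
bootstrap_null <- function(profile, centroids,
                           metric = c("spearman", "pearson", "euclidean"),
                           B = 1000, seed = NULL,
                           scheme = c("bootstrap", "permutation"),
                           enumerate = c("auto", "never", "always"),
                           enumerate_cap = 250000) {
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  enumerate <- match.arg(enumerate)
  profile <- check_profile(profile)
  centroids <- check_centroids(centroids)
  if (!is.numeric(B) || length(B) != 1L || B < 1) stop("'B' must be >= 1")
  B <- as.integer(B)
  cm <- centroids[names(profile), , drop = FALSE]
  n <- length(profile)

  n_assign <- n^n
  do_enum <- scheme == "bootstrap" &&
    (enumerate == "always" ||
     (enumerate == "auto" && is.finite(n_assign) && n_assign <= enumerate_cap))
  if (enumerate == "always" && (!is.finite(n_assign) || n_assign > enumerate_cap))
    stop("enumeration requested but n^n exceeds 'enumerate_cap'")

  if (do_enum) {
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    vals <- matrix(profile[t(idx)], nrow = n)   # n x n^n assignments
  } else {
    if (!is.null(seed)) set.seed(seed)
    draw <- function(m) {
      if (scheme == "bootstrap")
        matrix(sample.int(n, n * m, replace = TRUE), nrow = n)
      else
        replicate(m, sample.int(n))
    }
    vals <- matrix(profile[draw(B)], nrow = n)
  }
  n_redrawn <- 0L
  if (metric %in% c("spearman", "pearson")) {
    const <- apply(vals, 2L, function(v) max(v) == min(v))
    tries <- 0L
    while (any(const) && !do_enum && tries < 100L) {
      n_redrawn <- n_redrawn + sum(const)
      vals[, const] <- matrix(profile[draw(sum(const))], nrow = n)
      const <- apply(vals, 2L, function(v) max(v) == min(v))
      tries <- tries + 1L
    }
    if (any(const) && !do_enum)
      stop("could not draw non-constant resamples under a correlation metric")
    if (do_enum && any(const)) {
      vals <- vals[, !const, drop = FALSE]
      n_redrawn <- sum(const)   # dropped, not redrawn, in enumeration mode
    }
  }
  null <- distance_matrix(vals, cm, metric)
  list(null = null,
       expected = colMeans(null),
       B = nrow(null),
       scheme = scheme,
       exact = do_enum,
       n_redrawn = n_redrawn)
}

#' Simulation test and subtype assignment
#'
#' Compares each observed centroid distance with its resampling null. The
#' one-sided p-value (small distance = similar) uses the add-one rule
#' `p = (1 + #\{null <= observed\}) / (B + 1)`, so p is never 0. A subtype is
#' significant when its observed distance falls below the `tail_level`
#' quantile of its null. Assignment is the subtype minimizing the relative
#' distance observed/expected (ties: raw distance, then label order);
#' raw-distance assignment is available.
#'
#' @param observed named vector of observed distances (see
#'   [centroid_distance()]).
#' @param null bootstrap null from [bootstrap_null()], or a replicates x
#'   subtypes matrix.
#' @param tail_level lower-tail significance level (default 0.05).
#' @param assignment `"relative"` (default) or `"raw"`.
#' @param pooled if `TRUE`, p-values are computed against the null draws
#'   pooled across all subtype-centroid pairs instead of per subtype.
#' @return object of class `subtype_result`: list with `table` (data frame:
#'   subtype, observed, expected, relative, p_value, significant),
#'   `assigned`, `B`, `tail_level`, `pooled`.
#' @export
simulation_test <- function(observed, null, tail_level = 0.05,
                            assignment = c("relative", "raw"),
                            pooled = FALSE) {
  assignment <- match.arg(assignment)
  if (is.list(null) && !is.null(null$null)) null <- null$null
  if (!is.matrix(null) || nrow(null) < 1L)
    stop("'null' must be a non-empty replicates x subtypes matrix")
  if (tail_level <= 0 || tail_level >= 1)
    stop("'tail_level' must be in (0, 1)")
  subtypes <- colnames(null)
  if (is.null(subtypes)) subtypes <- names(observed)
  observed <- observed[subtypes]
  B <- nrow(null)
  expected <- colMeans(null)
  p <- if (pooled) {
    pool <- as.vector(null)
    vapply(observed, function(o) (1 + sum(pool <= o)) / (length(pool) + 1), 0)
  } else {
    vapply(subtypes, function(s) (1 + sum(null[, s] <= observed[s])) / (B + 1), 0)
  }
  cutoff <- if (pooled) {
    rep(stats::quantile(as.vector(null), tail_level, names = FALSE),
        length(subtypes))
  } else {
    apply(null, 2L, stats::quantile, probs = tail_level, names = FALSE)
  }
  relative <- observed / expected
  key <- if (assignment == "relative") relative else observed
  ord <- order(key, observed, subtypes)
  tab <- data.frame(subtype = subtypes,
                    observed = as.numeric(observed),
                    expected = as.numeric(expected),
                    relative = as.numeric(relative),
                    p_value = as.numeric(p),
                    significant = as.numeric(observed) < cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, assigned = subtypes[ord[1L]], B = B,
                 tail_level = tail_level, pooled = pooled),
            class = "subtype_result")
}

#' One-call nearest-centroid subtype classification
#'
#' Maps a fold-change profile onto the centroid signature (optionally through
#' a cross-species gene map), computes per-subtype distances, builds the
#' bootstrap null, and runs the simulation test.
#'
#' @inheritParams map_profile
#' @inheritParams bootstrap_null
#' @inheritParams simulation_test
#' @param gene_map optional source-to-target symbol map; `NULL` uses gene
#'   names as-is.
#' @return `subtype_result` (see [simulation_test()]) with an extra
#'   `n_mapped` element.
#' @export
classify_subtype <- function(profile, centroids, gene_map = NULL,
                             metric = c("spearman", "pearson", "euclidean"),
                             B = 1000, seed = NULL, tail_level = 0.05,
                             scheme = c("bootstrap", "permutation"),
                             assignment = c("relative", "raw"),
                             pooled = FALSE, min_fraction = 0.5) {
  metric <- match.arg(metric)
  if (is.null(gene_map)) {
    genes <- intersect(names(profile), rownames(centroids))
    gene_map <- data.frame(source = genes, target = genes,
                           stringsAsFactors = FALSE)
  }
  mapped <- map_profile(profile, gene_map, centroids,
                        min_fraction = min_fraction)
  obs <- centroid_distance(mapped, centroids, metric)
  nul <- bootstrap_null(mapped, centroids, metric, B = B, seed = seed,
                        scheme = scheme)
  res <- simulation_test(obs, nul, tail_level = tail_level,
                         assignment = assignment, pooled = pooled)
  res$n_mapped <- attr(mapped, "n_mapped")
  res
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("Nearest-centroid subtype assignment (B = %d%s)\n", x$B,
              if (isTRUE(x$pooled)) ", pooled null" else ""))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("assigned subtype: %s\n", x$assigned))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

check_centroids <- function(centroids) {
  if (is.data.frame(centroids)) centroids <- as.matrix(centroids)
  if (!is.matrix(centroids) || !is.numeric(centroids))
    stop("'centroids' must be a numeric matrix (signature genes x subtypes)")
  if (is.null(rownames(centroids)) || is.null(colnames(centroids)))
    stop("'centroids' needs gene rownames and subtype colnames")
  if (anyDuplicated(rownames(centroids))) stop("duplicate signature genes")
  if (ncol(centroids) < 2L) stop("need at least 2 subtypes")
  if (anyNA(centroids)) stop("centroids contain missing values")
  centroids
}

# distance of each column of vals (n x m resamples) to each centroid column
distance_matrix <- function(vals, cm, metric) {
  k <- colnames(cm)
  out <- switch(metric,
    spearman = {
      rv <- apply(vals, 2L, rank)
      if (!is.matrix(rv)) rv <- matrix(rv, nrow = nrow(vals))
      1 - t(stats::cor(apply(cm, 2L, rank), rv))
    },
    pearson = 1 - t(stats::cor(cm, vals)),
    euclidean = {
      m <- ncol(vals)
      d <- matrix(NA_real_, m, ncol(cm))
      for (j in seq_len(ncol(cm)))
        d[, j] <- sqrt(colSums((vals - cm[, j])^2))
      d
    })
  colnames(out) <- k
  out
}
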