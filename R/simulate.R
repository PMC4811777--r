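#' Simulate a bead-array-like expression experiment with planted truth
#'
#' Generates raw-scale intensities for several conditions with technical
#' duplicates and known planted log2 fold changes, emulating a small pooled
#' neural-stem-cell bead-array design: per gene a latent log2 baseline is
#' drawn once, condition effects are added on the log2 scale, each biological
#' sample gets `n_tech_dups` technical duplicates that are independent noisy
#' reads of the same latent sample, and intensities are emitted as
#' `2^log2value`. With `noise_sd = 0` technical duplicates are identical and
#' unplanted fold changes are exactly zero. All randomness is driven by
#' `seed` (R's default Mersenne-Twister generator), so identical calls are
#' bit-identical.
#'
#' @param n_genes number of genes; must be at least the number of planted
#'   genes.
#' @param conditions named integer vector: biological samples per condition.
#'   The first name is the reference condition. Default
#'   `c(wt = 1, p53null = 1, dblnull = 1)` — one pooled sample per genotype.
#' @param n_tech_dups technical duplicates per biological sample (default 2).
#' @param planted_logfc named list, one element per non-reference condition:
#'   a named numeric vector gene -> planted log2 fold change. Genes must
#'   exist in the gene universe (`gene0001` ... or supply `gene_ids`).
#' @param noise_sd additive Gaussian noise SD on the log2 scale
#'   (default 0.1).
#' @param gene_ids optional character vector of gene identifiers.
#' @param baseline_range range of the uniform log2 baseline (default
#'   `c(4, 14)`).
#' @param seed integer seed.
#' @return list with `values` (raw intensity matrix, genes x arrays),
#'   `annotation` (`sample_id`, `condition`, `replicate_group`), and `truth`
#'   (class `expression_truth`: `planted_logfc`, `noise_sd`, `seed`,
#'   `reference`).
#' @export
simulate_expression <- function(n_genes = 2000,
                                conditions = c(wt = 1, p53null = 1, dblnull = 1),
                                n_tech_dups = 2,
                                planted_logfc = list(),
                                noise_sd = 0.1,
                                gene_ids = NULL,
                                baseline_range = c(4, 14),
                                seed = 1) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("'conditions' must be a named vector (first name = reference)")
  reference <- names(conditions)[1L]
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) stop("'gene_ids' length must equal 'n_genes'")
  for (cond in names(planted_logfc)) {
    if (!cond %in% names(conditions))
      stop("planted condition not in design: ", cond)
    if (identical(cond, reference))
      stop("cannot plant effects in the reference condition")
    bad <- setdiff(names(planted_logfc[[cond]]), gene_ids)
    if (length(bad))
      stop("planted gene not in gene universe: ", bad[1L])
  }
  set.seed(seed)
  baseline <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
  names(baseline) <- gene_ids
  # planted effects must stay inside the dynamic range: a probe at the
  # intensity ceiling cannot show up-regulation (quantile normalization
  # would clip it), so planted genes get baselines leaving headroom
  all_planted <- unique(unlist(lapply(planted_logfc, names)))
  if (length(all_planted)) {
    margin <- 0.5
    for (g in all_planted) {
      effs <- c(0, vapply(planted_logfc,
                          function(v) if (g %in% names(v)) v[[g]] else 0, 0))
      lo_g <- baseline_range[1L] + margin - min(effs)
      hi_g <- baseline_range[2L] - margin - max(effs)
      if (lo_g < hi_g && (baseline[g] < lo_g || baseline[g] > hi_g))
        baseline[g] <- stats::runif(1, lo_g, hi_g)
    }
  }
  cols <- list(); ann <- list()
  for (cond in names(conditions)) {
    eff <- rep(0, n_genes); names(eff) <- gene_ids
    if (!is.null(planted_logfc[[cond]]))
      eff[names(planted_logfc[[cond]])] <- planted_logfc[[cond]]
    for (b in seq_len(conditions[[cond]])) {
      latent <- baseline + eff
      grp <- sprintf("%s_%d", cond, b)
      for (d in seq_len(n_tech_dups)) {
        id <- sprintf("%s_dup%d", grp, d)
        cols[[id]] <- latent + stats::rnorm(n_genes, 0, noise_sd)
        ann[[id]] <- data.frame(sample_id = id, condition = cond,
                                replicate_group = grp,
                                stringsAsFactors = FALSE)
      }
    }
  }
  values <- 2^do.call(cbind, cols)
  rownames(values) <- gene_ids
  list(values = values,
       annotation = do.call(rbind, c(ann, list(make.row.names = FALSE))),
       truth = structure(list(planted_logfc = planted_logfc,
                              noise_sd = noise_sd, seed = seed,
                              reference = reference),
                         class = "expression_truth"))
}

#' Simulate an ordered SNP-marker track with injected CNVs and a GC wave
#'
#' Places evenly spaced markers along each chromosome (positions
#' `spacing, 2*spacing, ...`), draws a smooth GC fraction per marker
#' (smoothed Gaussian random walk, clipped to `gc_range`), and builds the
#' LRR as the sum of the covering truth segment's mean shift, a GC wave
#' `wave_coefficient * (gc - median(gc))` (median over the whole track), and
#' Gaussian noise. BAF is drawn consistently with the copy-number state
#' (e.g. around 0, 0.5, 1 for the normal state). With `noise_sd = 0`,
#' `wave_coefficient = 0` and no segments, every LRR is exactly 0.
#'
#' @param chrom_lengths named numeric vector: chromosome -> length in bp.
#' @param marker_spacing distance between markers in bp (default 50000).
#' @param segments injected CNV truth: data frame with `chrom`, `start`,
#'   `end` (bp, 1-based inclusive), `state` (integer 0-4), `shift` (mean LRR
#'   shift). Segments must lie inside their chromosome and not overlap.
#'   `NULL` or empty means no CNVs.
#' @param wave_coefficient LRR units per unit of centered GC fraction
#'   (default 0).
#' @param noise_sd Gaussian LRR noise SD (default 0.15).
#' @param gc_range clipping range of the smooth GC process (default
#'   `c(0.3, 0.7)`).
#' @param seed integer seed.
#' @return list with `track` (data frame: `marker_id`, `chrom`, `pos`,
#'   `lrr`, `baf`, `gc`, `is_allelic`) and `truth` (class `cnv_truth`:
#'   `segments`, `wave_coefficient`, `noise_sd`, `seed`).
#' @export
simulate_marker_track <- function(chrom_lengths = c(chr1 = 100e6),
                                  marker_spacing = 50000,
                                  segments = NULL,
                                  wave_coefficient = 0,
                                  noise_sd = 0.15,
                                  gc_range = c(0.3, 0.7),
                                  seed = 1) {
  if (marker_spacing <= 0) stop("'marker_spacing' must be positive")
  if (is.null(names(chrom_lengths)))
    stop("'chrom_lengths' must be named by chromosome")
  if (is.null(segments))
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), state = integer(),
                           shift = numeric(), stringsAsFactors = FALSE)
  check_truth_segments(segments, chrom_lengths)
  set.seed(seed)
  rows <- list()
  for (ch in names(chrom_lengths)) {
    pos <- seq(marker_spacing, chrom_lengths[[ch]], by = marker_spacing)
    n <- length(pos)
    if (n == 0L) next
    gc <- smooth_gc(n, gc_range)
    shift <- rep(0, n); state <- rep(2L, n)
    ss <- segments[segments$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(ss))) {
      in_seg <- pos >= ss$start[k] & pos <= ss$end[k]
      shift[in_seg] <- ss$shift[k]
      state[in_seg] <- ss$state[k]
    }
    rows[[ch]] <- data.frame(
      marker_id = sprintf("%s_m%06d", ch, seq_len(n)),
      chrom = ch, pos = pos, lrr = shift, baf = simulate_baf(state),
      gc = gc, is_allelic = TRUE, state = state,
      stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  wave <- wave_coefficient * (track$gc - stats::median(track$gc))
  track$lrr <- track$lrr + wave + stats::rnorm(nrow(track), 0, noise_sd)
  track$state <- NULL
  list(track = track,
       truth = structure(list(segments = segments,
                              wave_coefficient = wave_coefficient,
                              noise_sd = noise_sd, seed = seed),
                         class = "cnv_truth"))
}

#' Simulate a cohort table of expression z-scores
#'
#' Wild-type samples draw z-scores from the standard normal; the mutant group
#' (a fixed `round(mutant_fraction * n_samples)` samples) is shifted by
#' `effect`. Subtype labels are assigned from a categorical distribution
#' resembling published GBM cohort composition.
#'
#' @param n_samples total samples; each group must end up with at least 2.
#' @param effect z-score shift of the mutant group (default 1).
#' @param mutant_fraction proportion of mutant samples, in (0, 1)
#'   (default 0.3).
#' @param subtype_probs named probability vector for subtype labels.
#' @param platform platform label stored in the table
#'   (default `"microarray"`).
#' @param seed integer seed.
#' @return data frame `sample_id`, `zscore`, `mutation_status` (`"mutant"` /
#'   `"wild-type"`), `subtype`, `platform`, with attribute `effect`.
#' @export
simulate_cohort <- function(n_samples = 100, effect = 1,
                            mutant_fraction = 0.3,
                            subtype_probs = c(GCiMP = 0.09, Proneural = 0.28,
                                              Neural = 0.16, Classical = 0.22,
                                              Mesenchymal = 0.25),
                            platform = "microarray", seed = 1) {
  if (mutant_fraction <= 0 || mutant_fraction >= 1)
    stop("'mutant_fraction' must be in (0, 1)")
  n_mut <- round(mutant_fraction * n_samples)
  n_wt <- n_samples - n_mut
  if (n_mut < 2L || n_wt < 2L)
    stop("each group needs at least 2 samples")
  set.seed(seed)
  status <- c(rep("mutant", n_mut), rep("wild-type", n_wt))
  z <- stats::rnorm(n_samples) + ifelse(status == "mutant", effect, 0)
  out <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n_samples)),
    zscore = z,
    mutation_status = status,
    subtype = sample(names(subtype_probs), n_samples, replace = TRUE,
                     prob = subtype_probs),
    platform = platform,
    stringsAsFactors = FALSE)
  attr(out, "effect") <- effect
  out
}

#' Simulate a centroid signature matrix
#'
#' Independent standard-normal centroid values over a synthetic gene
#' signature; a stand-in for a published subtype centroid set when testing
#' the classifier with planted truth.
#'
#' @param n_genes signature size (default 100).
#' @param subtypes subtype labels (default the four GBM expression
#'   subtypes).
#' @param sd centroid value SD (default 1).
#' @param seed integer seed.
#' @return numeric matrix, signature genes x subtypes.
#' @export
simulate_centroids <- function(n_genes = 100,
                               subtypes = c("Proneural", "Neural",
                                            "Classical", "Mesenchymal"),
                               sd = 1, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * length(subtypes), 0, sd),
         nrow = n_genes,
         dimnames = list(sprintf("SIG%04d", seq_len(n_genes)), subtypes))
}

#' Simulate a cross-species gene-symbol map
#'
#' Builds a source-to-target map covering a fraction of the target symbols,
#' mimicking incomplete mouse-to-human ortholog symbol matching. Source
#' symbols are lowercased targets with a species tag.
#'
#' @param targets character vector of target (signature) symbols.
#' @param frac_mapped fraction of targets with a mapped source
#'   (default 0.8).
#' @param seed integer seed.
#' @return data frame with columns `source`, `target`.
#' @export
simulate_gene_map <- function(targets, frac_mapped = 0.8, seed = 1) {
  set.seed(seed)
  keep <- sort(sample.int(length(targets), round(frac_mapped * length(targets))))
  data.frame(source = paste0("m", tolower(targets[keep])),
             target = targets[keep], stringsAsFactors = FALSE)
}

# ---- internal helpers -------------------------------------------------------

check_truth_segments <- function(segments, chrom_lengths) {
  req <- c("chrom", "start", "end", "state", "shift")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("'segments' needs columns: ", paste(req, collapse = ", "))
  if (nrow(segments) == 0L) return(invisible(segments))
  if (any(!segments$state %in% 0:4))
    stop("truth states must be integers in [0, 4]")
  for (ch in unique(segments$chrom)) {
    if (!ch %in% names(chrom_lengths))
      stop("truth segment on unknown chromosome: ", ch)
    ss <- segments[segments$chrom == ch, , drop = FALSE]
    ss <- ss[order(ss$start), , drop = FALSE]
    if (any(ss$start < 1 | ss$end > chrom_lengths[[ch]] | ss$start > ss$end))
      stop("truth segment outside chromosome bounds on ", ch)
    if (nrow(ss) > 1L && any(ss$start[-1L] <= ss$end[-nrow(ss)]))
      stop("overlapping truth segments on ", ch)
  }
  invisible(segments)
}

# smoothed Gaussian random walk rescaled into gc_range
smooth_gc <- function(n, gc_range) {
  w <- cumsum(stats::rnorm(n))
  k <- min(51L, if (n %% 2L == 0L) n - 1L else n)
  if (k >= 3L) {
    sm <- stats::filter(w, rep(1 / k, k), sides = 2L)
    sm <- as.numeric(sm)
    # fill edge NAs with nearest smoothed value
    idx <- which(!is.na(sm))
    if (length(idx)) {
      sm[seq_len(idx[1L] - 1L)] <- sm[idx[1L]]
      sm[seq.int(idx[length(idx)] + 1L, length.out = n - idx[length(idx)])] <-
        sm[idx[length(idx)]]
    } else sm <- w
  } else sm <- w
  mid <- mean(gc_range); halfspan <- diff(gc_range) / 2
  rng <- max(sm) - min(sm)
  if (rng == 0) return(rep(mid, n))
  scaled <- mid + (sm - mean(sm)) / rng * 2 * halfspan
  pmin(pmax(scaled, gc_range[1L]), gc_range[2L])
}

# BAF consistent with integer copy-number state, clipped to [0, 1]
simulate_baf <- function(state) {
  n <- length(state)
  centers <- vapply(state, function(s) {
    switch(as.character(s),
      "0" = stats::runif(1),                      # no signal: noise
      "1" = sample(c(0, 1), 1L),                  # single allele
      "2" = sample(c(0, 0.5, 1), 1L),             # AA/AB/BB
      "3" = sample(c(0, 1 / 3, 2 / 3, 1), 1L),    # three copies
      "4" = sample(c(0, 0.25, 0.5, 0.75, 1), 1L), # four copies
      0.5)
  }, 0)
  pmin(pmax(centers + stats::rnorm(n, 0, 0.02), 0), 1)
}
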