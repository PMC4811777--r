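#' Per-marker GC fraction in centered windows
#'
#' Fills the `gc` column of a marker track with the GC fraction of a window
#' of `window_bp` centered on each marker, from either a binned GC track or a
#' genome FASTA. Windows are truncated at chromosome ends and the fraction is
#' computed over the available span only.
#'
#' @param markers marker track data frame with at least `chrom` and `pos`
#'   (1-based bp).
#' @param gc_track binned GC source: data frame with `chrom`, `start`, `end`
#'   (1-based inclusive), `gc` (fraction in \[0,1\]); bins must cover every
#'   marker position.
#' @param fasta genome FASTA path or a `Biostrings::DNAStringSet` (requires
#'   the Biostrings package). Exactly one of `gc_track`/`fasta` must be given.
#' @param window_bp window size in bp (default 1e6).
#' @return `markers` with the `gc` column set.
#' @export
gc_windows <- function(markers, gc_track = NULL, fasta = NULL,
                       window_bp = 1e6) {
  markers <- check_markers(markers, need_gc = FALSE)
  if (window_bp <= 0) stop("'window_bp' must be positive")
  if (is.null(gc_track) == is.null(fasta))
    stop("supply exactly one of 'gc_track' or 'fasta'")
  half <- window_bp / 2
  gc <- rep(NA_real_, nrow(markers))

  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("the 'fasta' source requires the Biostrings package")
    seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
      Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    for (ch in unique(markers$chrom)) {
      if (!ch %in% names(seqs)) stop("chromosome absent from FASTA: ", ch)
      len <- length(seqs[[ch]])
      i <- which(markers$chrom == ch)
      pos <- markers$pos[i]
      if (any(pos < 1 | pos > len))
        stop("marker outside sequence bounds on ", ch)
      v <- Biostrings::Views(seqs[[ch]],
                             start = pmax(1, pos - half),
                             end = pmin(len, pos + half))
      gc[i] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1L]
    }
  } else {
    req <- c("chrom", "start", "end", "gc")
    if (!is.data.frame(gc_track) || !all(req %in% names(gc_track)))
      stop("'gc_track' needs columns: ", paste(req, collapse = ", "))
    for (ch in unique(markers$chrom)) {
      bins <- gc_track[gc_track$chrom == ch, , drop = FALSE]
      if (nrow(bins) == 0L) stop("no GC bins for chromosome ", ch)
      bins <- bins[order(bins$start), , drop = FALSE]
      lo <- min(bins$start); hi <- max(bins$end)
      i <- which(markers$chrom == ch)
      pos <- markers$pos[i]
      if (any(pos < lo | pos > hi))
        stop("marker outside sequence bounds on ", ch)
      ws <- pmax(lo, pos - half); we <- pmin(hi, pos + half)
      gc[i] <- vapply(seq_along(pos), function(j) {
        ov <- pmin(we[j], bins$end) - pmax(ws[j], bins$start) + 1
        ov[ov < 0] <- 0
        sum(ov * bins$gc) / sum(ov)
      }, 0)
    }
  }
  markers$gc <- gc
  markers
}

#' Correct Log-R-Ratio genomic waviness against GC content
#'
#' Genomic waviness is a long-range LRR oscillation that tracks regional GC
#' content — an array artifact, not copy number. The correction subtracts the
#' median-centered GC fraction multiplied by the coefficient that minimizes
#' the variance of the corrected LRR. That quadratic has the unique minimizer
#' `c* = Cov(lrr, gc - median(gc)) / Var(gc - median(gc))`, so the corrected
#' variance is never larger than the input variance. The fit is genome-wide
#' per sample over autosomal markers by default.
#'
#' @param track marker track data frame with `chrom`, `pos`, `lrr`, `gc`.
#' @param per_chromosome fit one coefficient per chromosome instead of
#'   genome-wide (default `FALSE`).
#' @param autosomes_only restrict the fit (and correction) to autosomal
#'   markers (default `TRUE`); non-autosomal markers pass through unchanged.
#' @return list with `fit` (data frame: scope, coefficient, gc_median,
#'   variance_before, variance_after) and `track` (input with `lrr` replaced
#'   by the corrected values).
#' @export
fit_waviness <- function(track, per_chromosome = FALSE, autosomes_only = TRUE) {
  track <- check_markers(track, need_gc = TRUE)
  sel <- if (autosomes_only) is_autosome(track$chrom) else
    rep(TRUE, nrow(track))
  if (sum(sel) < 3L) stop("need at least 3 markers to fit waviness")
  scopes <- if (per_chromosome) unique(track$chrom[sel]) else "genome"
  fits <- lapply(scopes, function(sc) {
    i <- if (per_chromosome) which(sel & track$chrom == sc) else which(sel)
    lrr <- track$lrr[i]
    g <- track$gc[i] - stats::median(track$gc[i])
    vb <- stats::var(lrr)
    if (stats::var(g) == 0) {
      warning("GC has zero variance in scope '", sc, "'; no correction applied")
      coef <- 0
    } else {
      coef <- stats::cov(lrr, g) / stats::var(g)
    }
    corrected <- lrr - coef * g
    list(i = i, corrected = corrected,
         row = data.frame(scope = sc, coefficient = coef,
                          gc_median = stats::median(track$gc[i]),
                          variance_before = vb,
                          variance_after = stats::var(corrected),
                          stringsAsFactors = FALSE))
  })
  out <- track
  for (f in fits) out$lrr[f$i] <- f$corrected
  list(fit = do.call(rbind, lapply(fits, `[[`, "row")), track = out)
}

#' Segment an LRR track into runs of constant mean
#'
#' Changepoint segmentation by recursive binary splitting: within each
#' candidate segment the split maximizing the pooled two-sample t-statistic
#' is accepted when its permutation p-value is below `alpha` and both sides
#' hold at least `min_markers` markers; accepted sides are split recursively.
#' Spurious splits are then merged back ("SD-undo"): adjacent segments whose
#' mean difference is below `undo_sd` noise standard deviations are merged,
#' weakest pair first, with the noise SD estimated robustly from successive
#' marker differences as `median(|diff|) / (sqrt(2) * 0.6745)`. This is a
#' documented approximation of circular binary segmentation with the sdundo
#' split-pruning rule; exact equivalence is not claimed.
#'
#' @param track marker track data frame with `chrom`, `pos`, `lrr`, sorted by
#'   (chrom, pos).
#' @param alpha permutation p-value threshold for accepting a split
#'   (default 0.01).
#' @param n_perm permutations per tested split (default 100).
#' @param min_markers minimum markers per segment side (default 5). A
#'   chromosome with fewer markers yields a single segment with a warning.
#' @param undo_sd SD-undo multiple (default 3); `0` disables undoing.
#' @param seed optional integer seed for the permutation draws.
#' @return segment data frame: `chrom`, `start`, `end` (1-based inclusive,
#'   first/last marker positions), `n_markers`, `mean_lrr`, `state` (`NA`
#'   until [call_states()]). Segments tile each chromosome's markers.
#' @export
segment_lrr <- function(track, alpha = 0.01, n_perm = 100, min_markers = 5,
                        undo_sd = 3, seed = NULL) {
  track <- check_markers(track, need_gc = FALSE)
  if (min_markers < 2L) stop("'min_markers' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  segs <- list()
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    x <- track$lrr[i]
    pos <- track$pos[i]
    n <- length(x)
    if (n < min_markers) {
      warning("chromosome ", ch, " has fewer than ", min_markers,
              " markers; single segment")
      bounds <- c(1L, n)
    } else {
      cuts <- split_recursive(x, alpha, n_perm, min_markers)
      bounds <- refine_boundaries(x, c(1L, cuts, n + 1L), min_markers)
      bounds <- undo_splits(x, bounds[-c(1L, length(bounds))], undo_sd)
      bounds <- refine_boundaries(x, bounds, min_markers)
    }
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    ends[length(ends)] <- n
    for (s in seq_along(starts)) {
      a <- starts[s]; b <- ends[s]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = pos[a], end = pos[b],
        n_markers = b - a + 1L, mean_lrr = mean(x[a:b]),
        state = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, segs)
}

#' Call five-state copy number from segment means
#'
#' Assigns the conventional integer coding — 0 homozygous loss, 1 hemizygous
#' loss, 2 normal, 3 gain, 4 amplification — by comparing each segment's mean
#' LRR with four ordered cut points `(t1, t2, t3, t4)`:
#' mean <= t1 gives 0; (t1, t2\] gives 1; (t2, t3) gives 2; \[t3, t4) gives 3;
#' >= t4 gives 4. The defaults reflect log2 single-copy expectations at
#' moderate sample purity and are deliberately tunable.
#'
#' @param segments segment data frame from [segment_lrr()].
#' @param thresholds strictly increasing numeric vector of length 4
#'   (default `c(-1.0, -0.3, 0.3, 0.9)`).
#' @return `segments` with the `state` column filled (integer 0-4).
#' @export
call_states <- function(segments, thresholds = c(-1.0, -0.3, 0.3, 0.9)) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("'thresholds' must be 4 strictly increasing cut points")
  m <- segments$mean_lrr
  t1 <- thresholds[1L]; t2 <- thresholds[2L]
  t3 <- thresholds[3L]; t4 <- thresholds[4L]
  segments$state <- ifelse(m <= t1, 0L,
                    ifelse(m <= t2, 1L,
                    ifelse(m <  t3, 2L,
                    ifelse(m <  t4, 3L, 4L))))
  segments
}

#' Filter called segments to reportable CNVs
#'
#' Keeps non-normal segments (state != 2) strictly longer than
#' `min_length_bp`, with segment length `end - start + 1` on 1-based
#' inclusive coordinates.
#'
#' @param segments called segment data frame (see [call_states()]).
#' @param min_length_bp minimum length in bp, strict (default 1e6).
#' @return data frame of reportable CNV segments (possibly empty).
#' @export
filter_cnvs <- function(segments, min_length_bp = 1e6) {
  if (anyNA(segments$state)) stop("states must be assigned before filtering")
  keep <- segments$state != 2L &
    (segments$end - segments$start + 1) > min_length_bp
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compress per-sample segmentations to comparable regions
#'
#' Takes the union of all samples' segment boundaries per chromosome and
#' reports, for every resulting region and sample, the copy-number state of
#' the sample's covering segment — a region-by-sample state table comparable
#' across arrays.
#'
#' @param segsets named list of called segment data frames, one per sample;
#'   all samples must cover the same chromosome set.
#' @return data frame with `chrom`, `start`, `end` and one state column per
#'   sample.
#' @export
compress_regions <- function(segsets) {
  if (!is.list(segsets) || length(segsets) < 1L)
    stop("'segsets' must be a non-empty list of segment tables")
  if (is.null(names(segsets)))
    names(segsets) <- sprintf("sample%02d", seq_along(segsets))
  chrom_sets <- lapply(segsets, function(s) sort(unique(s$chrom)))
  ref <- chrom_sets[[1L]]
  for (k in seq_along(chrom_sets)) {
    d <- c(setdiff(ref, chrom_sets[[k]]), setdiff(chrom_sets[[k]], ref))
    if (length(d))
      stop("inconsistent chromosome sets across samples; differing: ",
           paste(unique(d), collapse = ", "))
  }
  rows <- list()
  for (ch in ref) {
    cuts <- sort(unique(unlist(lapply(segsets, function(s) {
      ss <- s[s$chrom == ch, , drop = FALSE]
      c(ss$start, ss$end + 1)
    }))))
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L] - 1
    states <- sapply(segsets, function(s) {
      ss <- s[s$chrom == ch, , drop = FALSE]
      vapply(starts, function(p) {
        hit <- which(ss$start <= p & ss$end >= p)
        if (length(hit)) as.integer(ss$state[hit[1L]]) else NA_integer_
      }, integer(1L))
    })
    if (!is.matrix(states)) states <- matrix(states, nrow = length(starts),
                                             dimnames = list(NULL, names(segsets)))
    rows[[ch]] <- data.frame(chrom = ch, start = starts, end = ends, states,
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- internal helpers -------------------------------------------------------

is_autosome <- function(chrom) {
  !toupper(sub("^CHR", "", toupper(chrom))) %in% c("X", "Y", "M", "MT")
}

check_markers <- function(track, need_gc = FALSE) {
  req <- c("chrom", "pos", "lrr", if (need_gc) "gc")
  if (!is.data.frame(track) || !all(req %in% names(track)))
    stop("marker track needs columns: ", paste(req, collapse = ", "))
  ord <- order(match(track$chrom, unique(track$chrom)), track$pos)
  if (!identical(ord, seq_len(nrow(track))))
    stop("markers must be sorted by (chromosome, position)")
  dup <- stats::aggregate(track$pos, list(track$chrom),
                          function(p) anyDuplicated(p) > 0L)$x
  if (any(dup)) stop("duplicate marker positions within a chromosome")
  if (need_gc && (anyNA(track$gc) || any(track$gc < 0 | track$gc > 1)))
    stop("'gc' must be present and within [0, 1]")
  track
}

# max pooled-t split of x restricted to sides >= min_markers
best_split <- function(x, min_markers) {
  n <- length(x)
  ks <- seq.int(min_markers, n - min_markers)
  if (length(ks) == 0L || ks[1L] > ks[length(ks)]) return(NULL)
  s <- cumsum(x); s2 <- cumsum(x^2)
  n1 <- ks; n2 <- n - ks
  m1 <- s[ks] / n1; m2 <- (s[n] - s[ks]) / n2
  ss1 <- s2[ks] - s[ks]^2 / n1
  ss2 <- (s2[n] - s2[ks]) - (s[n] - s[ks])^2 / n2
  s2p <- (ss1 + ss2) / (n - 2)
  tt <- abs(m1 - m2) / sqrt(pmax(s2p, .Machine$double.xmin) * (1 / n1 + 1 / n2))
  tt[s2p <= 0 & abs(m1 - m2) > 0] <- Inf
  tt[s2p <= 0 & abs(m1 - m2) == 0] <- 0
  j <- which.max(tt)
  list(k = ks[j], t = tt[j])
}

# recursive binary splitting with a permutation acceptance test;
# returns sorted interior cut indices (segment boundaries in 1..n index space)
split_recursive <- function(x, alpha, n_perm, min_markers) {
  cuts <- integer(0)
  stack <- list(c(1L, length(x)))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- rg[1L]; b <- rg[2L]
    seg <- x[a:b]
    if (length(seg) < 2L * min_markers) next
    bs <- best_split(seg, min_markers)
    if (is.null(bs) || bs$t == 0) next
    perm_t <- vapply(seq_len(n_perm), function(...) {
      ps <- best_split(sample(seg), min_markers)
      if (is.null(ps)) 0 else ps$t
    }, 0)
    p <- (1 + sum(perm_t >= bs$t)) / (n_perm + 1)
    if (p < alpha) {
      cut <- a + bs$k   # first index of the right-hand segment
      cuts <- c(cuts, cut)
      stack[[length(stack) + 1L]] <- c(a, cut - 1L)
      stack[[length(stack) + 1L]] <- c(cut, b)
    }
  }
  sort(cuts)
}

# re-optimize each interior boundary within its two flanking segments:
# greedy binary splitting localizes a cut while the flank still contains a
# second changepoint, so each cut is re-fit as the single best split of the
# union of its two adjacent segments, iterating until stable
refine_boundaries <- function(x, bounds, min_markers, max_iter = 5L) {
  if (length(bounds) <= 2L) return(bounds)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (i in seq.int(2L, length(bounds) - 1L)) {
      a <- bounds[i - 1L]
      c_ <- bounds[i + 1L] - 1L
      seg <- x[a:c_]
      if (length(seg) < 2L * min_markers) next
      bs <- best_split(seg, min_markers)
      if (is.null(bs)) next
      new_cut <- a + bs$k
      if (new_cut != bounds[i]) {
        bounds[i] <- new_cut
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bounds
}

# SD-undo: merge adjacent segments, weakest mean-difference first, while the
# difference is below undo_sd * robust noise SD; returns segment start
# boundaries c(1, cuts..., n+1)
undo_splits <- function(x, cuts, undo_sd) {
  bounds <- c(1L, cuts, length(x) + 1L)
  if (undo_sd <= 0 || length(bounds) <= 2L) return(bounds)
  sd_noise <- stats::median(abs(diff(x))) / (sqrt(2) * 0.6745)
  if (!is.finite(sd_noise) || sd_noise <= 0) return(bounds)
  seg_mean <- function(b) {
    vapply(seq_len(length(b) - 1L),
           function(i) mean(x[b[i]:(b[i + 1L] - 1L)]), 0)
  }
  repeat {
    if (length(bounds) <= 2L) break
    m <- seg_mean(bounds)
    d <- abs(diff(m))
    j <- which.min(d)
    if (d[j] < undo_sd * sd_noise) {
      bounds <- bounds[-(j + 1L)]
    } else break
  }
  bounds
}
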