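test_that("GC windows average a binned track with end truncation", {
  gc_track <- data.frame(chrom = "chr1",
                         start = c(1, 500001),
                         end = c(500000, 1000000),
                         gc = c(1, 0))   # left half 100% GC, right half 0%
  mk <- toy_track(rep(0, 3))
  mk$pos <- c(250000, 500001, 999000)
  m <- gc_windows(mk, gc_track = gc_track, window_bp = 1e6)
  # centered marker: equal overlap of both halves
  expect_equal(m$gc[2], 0.5, tolerance = 1e-6)
  # marker near the start: window truncated, mostly GC-rich half
  expect_gt(m$gc[1], 0.6)
  # marker near the end: mostly GC-poor half
  expect_lt(m$gc[3], 0.1)
  # uniform source gives the constant everywhere
  u <- gc_windows(mk, gc_track = data.frame(chrom = "chr1", start = 1,
                                            end = 1e6, gc = 0.5))
  expect_equal(u$gc, rep(0.5, 3))
  mk_bad <- mk; mk_bad$pos[3] <- 2e6
  expect_error(gc_windows(mk_bad, gc_track = gc_track), "outside")
})

test_that("GC windows from FASTA match exact base counting on a toy sequence", {
  skip_if_not_installed("Biostrings")
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 500), strrep("A", 500))))
  mk <- toy_track(rep(0, 1)); mk$pos <- 500
  out <- gc_windows(mk, fasta = seqs, window_bp = 200)
  # window [400, 600]: 101 G then 100 A
  expect_equal(out$gc, 101 / 201, tolerance = 1e-12)
})

test_that("waviness coefficient has zero-covariance and perfectly-explained degenerate cases", {
  # lrr orthogonal to centered gc: coefficient 0, output unchanged
  trk <- toy_track(lrr = c(1, -1, 1, -1), gc = c(0.6, 0.6, 0.4, 0.4))
  fw <- fit_waviness(trk)
  expect_equal(fw$fit$coefficient, 0, tolerance = 1e-12)
  expect_equal(fw$track$lrr, trk$lrr)
  # lrr = 0.4 * centered gc exactly: coefficient 0.4, zero residual variance
  gc <- c(0.3, 0.45, 0.5, 0.62, 0.7)
  g <- gc - median(gc)
  trk2 <- toy_track(lrr = 0.4 * g, gc = gc)
  fw2 <- fit_waviness(trk2)
  expect_equal(fw2$fit$coefficient, 0.4, tolerance = 1e-12)
  expect_equal(fw2$fit$variance_after, 0, tolerance = 1e-15)
  expect_equal(fw2$track$lrr, rep(0, 5), tolerance = 1e-12)
  # constant gc: warning, no correction
  trk3 <- toy_track(lrr = rnorm(5), gc = rep(0.5, 5))
  expect_warning(fw3 <- fit_waviness(trk3), "zero variance")
  expect_equal(fw3$track$lrr, trk3$lrr)
})

test_that("waviness fit never increases variance and beats a brute-force grid", {
  set.seed(41)
  for (s in 1:5) {
    sim <- simulate_marker_track(c(chr1 = 25e6), 50000, NULL,
                                 wave_coefficient = runif(1, -1, 1),
                                 noise_sd = 0.2, seed = s)
    fw <- fit_waviness(sim$track)
    expect_lte(fw$fit$variance_after, fw$fit$variance_before)
    g <- sim$track$gc - median(sim$track$gc)
    grid <- seq(-5, 5, by = 0.01)
    vgrid <- vapply(grid, function(cc) var(sim$track$lrr - cc * g), 0)
    expect_lt(abs(fw$fit$coefficient - grid[which.min(vgrid)]), 0.01 + 1e-9)
    expect_lte(fw$fit$variance_after, min(vgrid) + 1e-12)
    # closed form equals the covariance ratio to 1e-10
    expect_equal(fw$fit$coefficient, cov(sim$track$lrr, g) / var(g),
                 tolerance = 1e-10)
  }
})

test_that("non-autosomal markers are excluded from the waviness fit", {
  set.seed(43)
  aut <- toy_track(rnorm(100, 0, 0.1), gc = runif(100, 0.3, 0.7))
  sex <- toy_track(rnorm(50, 5, 0.1), gc = runif(50, 0.3, 0.7), chrom = "chrX")
  both <- rbind(aut, sex)
  fw <- fit_waviness(both)
  fw_aut <- fit_waviness(aut)
  expect_equal(fw$fit$coefficient, fw_aut$fit$coefficient)
  expect_equal(fw$track$lrr[101:150], sex$lrr)   # untouched
})

test_that("segmentation returns one segment for constant signal and exact noiseless steps", {
  cst <- toy_track(rep(0.2, 200))
  segs <- segment_lrr(cst, seed = 1)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_markers, 200L)
  expect_equal(segs$mean_lrr, 0.2)

  step <- toy_track(c(rep(0, 100), rep(1, 100)))
  segs2 <- segment_lrr(step, seed = 1)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$n_markers, c(100L, 100L))
  expect_equal(segs2$mean_lrr, c(0, 1))
  expect_equal(segs2$start, c(50000, 100 * 50000 + 50000))
})

test_that("SD-undo merges sub-threshold splits and keeps supra-threshold ones", {
  set.seed(47)
  x <- c(rnorm(100, 0, 0.05), rnorm(100, 0.1, 0.05), rnorm(100, 1, 0.05))
  trk <- toy_track(x)
  # noise SD ~ 0.05: threshold 3*0.05 = 0.15 swallows the 0.1 step
  s3 <- segment_lrr(trk, undo_sd = 3, seed = 5)
  expect_equal(nrow(s3), 2L)
  expect_equal(s3$mean_lrr[2], 1, tolerance = 0.05)
  # threshold 1*0.05 keeps all three levels
  s1 <- segment_lrr(trk, undo_sd = 1, seed = 5)
  expect_equal(nrow(s1), 3L)
})

test_that("segmentation tiles the marker index space per chromosome", {
  set.seed(53)
  truth <- data.frame(chrom = "chr1", start = 5e6 + 1, end = 9e6,
                      state = 1L, shift = -0.8)
  sim <- simulate_marker_track(c(chr1 = 20e6, chr2 = 10e6), 50000, truth,
                               0.5, 0.15, seed = 3)
  segs <- segment_lrr(sim$track, seed = 4)
  for (ch in c("chr1", "chr2")) {
    n_ch <- sum(sim$track$chrom == ch)
    ss <- segs[segs$chrom == ch, ]
    expect_equal(sum(ss$n_markers), n_ch)
    # contiguous: each segment starts at the marker after the previous end
    pos <- sim$track$pos[sim$track$chrom == ch]
    idx_start <- match(ss$start, pos); idx_end <- match(ss$end, pos)
    expect_equal(idx_start[-1], idx_end[-length(idx_end)] + 1L)
  }
  few <- toy_track(rnorm(3))
  expect_warning(sf <- segment_lrr(few, min_markers = 5, seed = 1), "fewer")
  expect_equal(nrow(sf), 1L)
})

test_that("state calling maps segment means through the published coding", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 2,
                     n_markers = 1L,
                     mean_lrr = c(-1.2, -0.5, 0.1, 0.5, 1.1),
                     state = NA_integer_)
  called <- call_states(segs)
  expect_equal(called$state, c(0L, 1L, 2L, 3L, 4L))
  # boundary semantics: <= t1 -> 0, (t1,t2] -> 1, [t3,t4) -> 3, >= t4 -> 4
  b <- data.frame(chrom = "c", start = 1, end = 2, n_markers = 1L,
                  mean_lrr = c(-1.0, -0.3, 0.3, 0.9), state = NA_integer_)
  expect_equal(call_states(b)$state, c(0L, 1L, 3L, 4L))
  expect_error(call_states(segs, thresholds = c(0, -1, 1, 2)), "increasing")
})

test_that("CNV reporting filter is strictly greater than 1 Mb and excludes normal state", {
  segs <- data.frame(
    chrom = "chr1",
    start = c(1, 2e6, 4e6, 6e6, 10e6),
    end = c(1 + 0.5e6 - 1, 2e6 + 1e6 - 1, 4e6 + 1.5e6 - 1, 6e6 + 3e6 - 1,
            10e6 + 5e6 - 1),
    n_markers = 10L,
    mean_lrr = c(0.5, 0.5, 0.5, 0.5, 0),
    state = c(3L, 3L, 3L, 3L, 2L))
  rep <- filter_cnvs(segs)
  # lengths 0.5, 1.0, 1.5, 3.0 Mb (state 3) and a 5 Mb normal segment:
  # exactly the 1.5 and 3.0 Mb gains pass
  expect_equal(rep$start, c(4e6, 6e6))
  all_normal <- segs; all_normal$state <- 2L
  expect_equal(nrow(filter_cnvs(all_normal)), 0L)
})

test_that("region compression takes the breakpoint union across samples", {
  sA <- data.frame(chrom = "chr1", start = c(1, 10e6 + 1), end = c(10e6, 30e6),
                   n_markers = 1L, mean_lrr = 0, state = c(2L, 3L))
  sB <- data.frame(chrom = "chr1", start = c(1, 15e6 + 1), end = c(15e6, 30e6),
                   n_markers = 1L, mean_lrr = 0, state = c(1L, 2L))
  reg <- compress_regions(list(A = sA, B = sB))
  expect_equal(nrow(reg), 3L)
  expect_equal(reg$start, c(1, 10e6 + 1, 15e6 + 1))
  expect_equal(reg$A, c(2L, 3L, 3L))
  expect_equal(reg$B, c(1L, 1L, 2L))
  # single sample: regions equal its segments
  reg1 <- compress_regions(list(A = sA))
  expect_equal(reg1$start, sA$start)
  expect_equal(reg1$A, sA$state)
  # identical segmentations: idempotent
  reg2 <- compress_regions(list(A = sA, B = sA))
  expect_equal(reg2$start, sA$start)
  sC <- sA; sC$chrom <- "chr2"
  expect_error(compress_regions(list(A = sA, C = sC)), "inconsistent")
})

test_that("injected CNVs are recovered end to end with wave correction", {
  # genome-scale track: the genome-wide wave fit needs many independent GC
  # excursions so injected CNVs cannot confound the coefficient
  spacing <- 50000
  truth <- data.frame(chrom = "chr1",
                      start = c(20e6 + 1, 60e6 + 1), end = c(24e6, 63e6),
                      state = c(1L, 3L), shift = c(-0.6, 0.7))
  sim <- simulate_marker_track(c(chr1 = 100e6, chr2 = 80e6), spacing, truth,
                               wave_coefficient = 0.8, noise_sd = 0.15,
                               seed = 19)
  fw <- fit_waviness(sim$track)
  segs <- call_states(segment_lrr(fw$track, seed = 20))
  rep <- filter_cnvs(segs)
  eb <- expected_seg_bounds(truth, spacing)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$state, truth$state)
  expect_true(all(abs(rep$start - eb$start) <= 2 * spacing))
  expect_true(all(abs(rep$end - eb$end) <= 2 * spacing))
})

test_that("BED export shifts to 0-based half-open coordinates", {
  segs <- data.frame(chrom = "chr1", start = 50000, end = 100000,
                     n_markers = 2L, mean_lrr = 0.5, state = 3L)
  path <- tempfile(fileext = ".bed")
  write_bed(segs, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 49999)
  expect_equal(bed$V3, 100000)
  expect_identical(bed$V4, "state3")
})
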