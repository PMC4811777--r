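test_that("glog transform matches the closed form and degenerates to log2", {
  m <- toy_matrix(c(8, 2, 4, 16), genes = c("g1", "g2"))
  expect_equal(glog_transform(m), log2(m), ignore_attr = FALSE)
  expect_equal(glog_transform(toy_matrix(8, "g1", ), 0)[1, 1], 3.0)

  # frozen values from an independent high-precision evaluation of
  # log2((x + sqrt(x^2 + c^2)) / 2) at c = 10
  x <- toy_matrix(c(1, 10, 100, 1000), genes = sprintf("g%d", 1:4))
  expect_equal(unname(glog_transform(x, 10)[, 1]),
               c(2.4659582254269666, 3.5934813980509743,
                 6.6474494767617203, 9.9658203506856578),
               tolerance = 1e-14)

  # monotone: within-sample ranking preserved for any glog_c
  set.seed(11)
  r <- matrix(2^runif(60, 1, 12), 20, 3,
              dimnames = list(sprintf("g%d", 1:20), c("a", "b", "c")))
  for (cc in c(0, 5, 50)) {
    tr <- glog_transform(r, cc)
    for (j in 1:3) expect_identical(order(tr[, j]), order(r[, j]))
  }
})

test_that("glog transform rejects non-positive values with coordinates", {
  m <- toy_matrix(c(8, -1, 4, 16), genes = c("g1", "g2"))
  expect_error(glog_transform(m), "g2.*s1")
})

test_that("quantile normalization reproduces the hand-worked example", {
  m <- toy_matrix(c(2, 4, 6, 4, 8, 12), genes = c("g1", "g2", "g3"),
                  samples = c("A", "B"))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "A"]), c(3, 6, 9))
  expect_equal(unname(qn[, "B"]), c(3, 6, 9))
})

test_that("quantile normalization is idempotent and a fixed point on identical samples", {
  set.seed(7)
  m <- matrix(rnorm(400, 8, 2), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
  qn <- quantile_normalize(m)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # identical sorted columns and identical column sums afterwards
  sorted <- apply(qn, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(colSums(qn), colSums(qn)[c(2, 3, 4, 1)], ignore_attr = TRUE)
  same <- m[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(quantile_normalize(same), same)
  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "at least 2")
})

test_that("quantile normalization agrees exactly with the limma reference on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(13)
  m <- matrix(rnorm(300, 8, 2), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  mine <- quantile_normalize(m)
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("ties get the mean of the reference values they span", {
  m <- toy_matrix(c(1, 1, 4, 2, 6, 10), genes = c("g1", "g2", "g3"),
                  samples = c("A", "B"))
  qn <- quantile_normalize(m)
  ref <- unname(rowMeans(apply(m, 2, sort)))    # 1.5, 3.5, 7
  expect_equal(unname(qn[, "A"]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(unname(qn[, "B"]), ref)
})

test_that("duplicate collapsing averages groups and reports correlations", {
  set.seed(21)
  lat <- rnorm(2000, 8, 2)
  m <- cbind(d1 = lat + rnorm(2000, 0, 0.05),
             d2 = lat + rnorm(2000, 0, 0.05),
             solo = rnorm(2000, 8, 2))
  rownames(m) <- sprintf("g%04d", 1:2000)
  ann <- toy_annotation(c("d1", "d2", "solo"), c("mut", "mut", "wt"),
                        c("mut_1", "mut_1", "wt_1"))
  res <- collapse_duplicates(m, ann)
  expect_identical(colnames(res$values), c("mut_1", "wt_1"))
  expect_equal(res$values[, "mut_1"], rowMeans(m[, 1:2]))
  expect_equal(res$values[, "wt_1"], m[, "solo"])   # size-1 group passes through

  # textbook Pearson formula as the independent oracle
  a <- m[, 1]; b <- m[, 2]
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$correlations$correlation[1], r_manual, tolerance = 1e-12)
})

test_that("identical duplicates give correlation 1 and the shared column", {
  set.seed(3)
  v <- rnorm(50, 8, 2)
  m <- cbind(d1 = v, d2 = v)
  rownames(m) <- sprintf("g%02d", 1:50)
  ann <- toy_annotation(c("d1", "d2"), c("wt", "wt"), c("wt_1", "wt_1"))
  res <- collapse_duplicates(m, ann)
  expect_equal(res$correlations$correlation, 1)
  expect_equal(unname(res$values[, 1]), unname(v))
})

test_that("duplicate QC warns below the floor and errors in strict mode; cross-condition groups error", {
  set.seed(5)
  lat <- rnorm(100, 8, 2)
  m <- cbind(d1 = lat + rnorm(100, 0, 1), d2 = lat + rnorm(100, 0, 1))
  rownames(m) <- sprintf("g%03d", 1:100)
  ann <- toy_annotation(c("d1", "d2"), c("wt", "wt"), c("w", "w"))
  expect_warning(collapse_duplicates(m, ann), "correlation floor")
  expect_error(collapse_duplicates(m, ann, strict = TRUE), "correlation floor")
  ann_bad <- toy_annotation(c("d1", "d2"), c("wt", "mut"), c("w", "w"))
  expect_error(collapse_duplicates(m, ann_bad), "spanning")
})

test_that("fold-change profiles are condition mean minus reference mean", {
  m <- toy_matrix(c(3, 5, 4, 7), genes = c("g1", "g2"),
                  samples = c("wt_1", "mut_1"))
  ann <- data.frame(sample_id = c("wt_1", "mut_1"),
                    condition = c("wt", "mut"), stringsAsFactors = FALSE)
  fc <- fold_change_profile(m, ann, "mut", "wt")
  expect_equal(unname(fc), c(1, 2), ignore_attr = TRUE)
  expect_identical(attr(fc, "condition"), "mut")
  # identical groups give zero everywhere
  m2 <- m; m2[, 2] <- m[, 1]
  expect_equal(unname(fold_change_profile(m2, ann, "mut", "wt")), c(0, 0),
               ignore_attr = TRUE)
  expect_error(fold_change_profile(m, ann, "nope", "wt"), "unknown condition")
})

test_that("deregulated selection applies the strict 1.5-fold rule and is antitone in threshold", {
  fc <- c(g1 = 0.7, g2 = -0.6, g3 = 0.3)
  d <- select_deregulated(fc, 1.5)
  expect_identical(d$gene[d$direction == "up"], "g1")
  expect_identical(d$gene[d$direction == "down"], "g2")
  expect_identical(attr(d, "counts"), c(up = 1L, down = 1L))
  # boundary: |logFC| exactly log2(1.5) is NOT selected
  expect_equal(nrow(select_deregulated(c(gx = log2(1.5)), 1.5)), 0L)
  expect_equal(nrow(select_deregulated(c(g1 = 0, g2 = 0), 1.5)), 0L)
  set.seed(17)
  fcs <- setNames(rnorm(200, 0, 1), sprintf("g%03d", 1:200))
  for (th in c(1.2, 1.5, 2, 3)) {
    lo <- select_deregulated(fcs, th)$gene
    hi <- select_deregulated(fcs, th + 0.5)$gene
    expect_true(all(hi %in% lo))
  }
})

test_that("rescue classification uses the complementary non-strict band", {
  d <- select_deregulated(c(g1 = 0.7, g2 = -0.9), 1.5)
  r <- classify_rescue(d, c(g1 = 0.2, g2 = -0.8))
  expect_identical(r$gene[r$rescued], "g1")
  expect_equal(attr(r, "summary")$fraction_overall, 0.5)
  # all-zero secondary: everything rescued; identical secondary: nothing
  r_all <- classify_rescue(d, c(g1 = 0, g2 = 0))
  expect_equal(attr(r_all, "summary")$fraction_overall, 1)
  r_none <- classify_rescue(d, c(g1 = 0.7, g2 = -0.9))
  expect_equal(attr(r_none, "summary")$fraction_overall, 0)
  # boundary value exactly log2(1.5) counts as rescued (non-strict)
  r_b <- classify_rescue(d, c(g1 = log2(1.5), g2 = -2))
  expect_true(r_b$rescued[r_b$gene == "g1"])
  expect_error(classify_rescue(d, c(g1 = 0.1)), "g2")
})

test_that("rescued and not-rescued partition the deregulated set", {
  set.seed(31)
  fc1 <- setNames(rnorm(500, 0, 1.2), sprintf("g%03d", 1:500))
  fc2 <- setNames(rnorm(500, 0, 1.2), names(fc1))
  d <- select_deregulated(fc1)
  r <- classify_rescue(d, fc2)
  s <- attr(r, "summary")
  expect_equal(s$rescued_up + sum(!r$rescued & r$direction == "up"), s$total_up)
  expect_equal(sum(r$rescued) + sum(!r$rescued), nrow(d))
  expect_true(s$fraction_overall >= 0 && s$fraction_overall <= 1)
  # gene ordering of the input profile is preserved
  expect_identical(r$gene, names(fc1)[names(fc1) %in% r$gene])
})
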