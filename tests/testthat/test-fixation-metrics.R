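test_that("compute_parameters matches analytic values on fixtures", {
  g <- tracking_grid(c(50.5, 50.5), px_per_mm = 10)
  # one 10x10 square centered on the grid center -> SA 100, SP 40, ACD 0
  p <- compute_parameters(extract_clusters(small_mask(46, 46, 10, g)))
  expect_equal(p$sa, 100)
  expect_equal(p$sp, 40)
  expect_equal(p$acd, 0)

  # overlapping 4x4 pair: one merged cluster, SA 24, ACD = its centroid dist
  cs <- extract_clusters(small_mask(c(20, 22), c(20, 20), 4, g))
  p2 <- compute_parameters(cs)
  expect_equal(p2$sa, 24)
  expect_equal(p2$acd, cs$clusters$dist_px)
})

test_that("ACD is the area-weighted mean centroid distance", {
  # clusters (area 48, dist 10) and (area 16, dist 20) -> 12.5
  k <- c(48, 16); d <- c(10, 20)
  expect_equal(sum(k * d) / sum(k), 12.5)
  # realized geometrically: a 12x4 strip (three merged 4x4s) plus a lone 4x4
  g <- tracking_grid(c(101, 101), px_per_mm = 10)
  cs <- extract_clusters(small_mask(c(91, 95, 99, 40), c(89, 89, 89, 120),
                                    4, g))
  expect_identical(sort(cs$clusters$area_px), c(16L, 48L))
  p <- compute_parameters(cs)
  expect_equal(p$acd, sum(cs$clusters$area_px * cs$clusters$dist_px) /
                 sum(cs$clusters$area_px))
  expect_lte(p$acd, max(cs$clusters$dist_px))
})

test_that("single-cluster ACD equals that cluster's centroid distance", {
  g <- small_grid()
  for (s in c(2, 5, 9)) {
    cs <- extract_clusters(small_mask(12, 20, s, g))
    p <- compute_parameters(cs)
    expect_equal(p$acd, cs$clusters$dist_px)
  }
})

test_that("FIS formula evaluates the published coefficients", {
  expect_equal(compute_fis(plot_params(0, 0, 0))$fis_raw, 4.458)
  expect_equal(compute_fis(plot_params(0, 0, 0))$anxiety_class,
               factor("normal", levels = anxiety_levels()))
  # Table-style medians of an untroubled cohort land just above the
  # normal/borderline boundary
  f <- compute_fis(plot_params(490.50, 110.00, 12.08))
  expect_equal(f$fis_raw, 12.45354, tolerance = 1e-10)
  expect_equal(as.character(f$anxiety_class), "borderline")
  # unit effect of SA alone
  expect_equal(compute_fis(plot_params(1000, 0, 0))$fis_raw -
                 compute_fis(plot_params(0, 0, 0))$fis_raw, 5)
})

test_that("FIS partial differences recover the coefficients exactly", {
  base <- plot_params(200, 80, 15)
  f0 <- compute_fis(base)$fis_raw
  expect_equal(compute_fis(plot_params(201, 80, 15))$fis_raw - f0, 0.005)
  expect_equal(compute_fis(plot_params(200, 81, 15))$fis_raw - f0, 0.027)
  expect_equal(compute_fis(plot_params(200, 80, 16))$fis_raw - f0, 0.213)
  # strictly increasing in each argument
  expect_gt(compute_fis(plot_params(250, 80, 15))$fis_raw, f0)
  expect_gt(compute_fis(plot_params(200, 90, 15))$fis_raw, f0)
  expect_gt(compute_fis(plot_params(200, 80, 20))$fis_raw, f0)
})

test_that("scale value rounds half-up and clips to [0, 90]", {
  expect_identical(compute_fis(plot_params(0, 0, 0))$fis_scale, 4L)  # 4.458
  big <- compute_fis(plot_params(30000, 0, 0))       # raw 154.458
  expect_identical(big$fis_scale, 90L)
  mid <- compute_fis(plot_params(1608.4, 0, 0))      # raw 12.5 -> 13
  expect_identical(mid$fis_scale, 13L)
})

test_that("classification boundaries follow the 0-90 scale bands", {
  expect_equal(as.character(classify_fis(c(12, 13, 36, 37))),
               c("normal", "borderline", "borderline", "case"))
  expect_equal(as.character(classify_fis(4.458)), "normal")
  expect_error(classify_fis(NaN), "finite")
  expect_error(classify_fis(Inf), "finite")
  p2 <- plot_params(10, 5, 2)
  p2$sa <- -1
  expect_error(compute_fis(p2), "non-negative")
})

test_that("classify_fis is consistent with compute_fis on random params", {
  set.seed(7)
  for (i in 1:50) {
    p <- plot_params(runif(1, 0, 6000), runif(1, 0, 1200), runif(1, 0, 100))
    f <- compute_fis(p)
    expect_identical(classify_fis(f$fis_raw), f$anxiety_class)
  }
})

test_that("ACD is invariant to a common scaling of cluster areas", {
  areas <- c(48, 16, 30); d <- c(10, 20, 5)
  acd1 <- sum(areas * d) / sum(areas)
  acd2 <- sum(3.7 * areas * d) / sum(3.7 * areas)
  expect_equal(acd1, acd2)
})

test_that("HADS scoring sums items and bands the sub-score", {
  expect_identical(score_hads(rep(0, 7))$sub_score, 0L)
  expect_equal(as.character(score_hads(rep(0, 7))$hads_class), "normal")
  expect_identical(score_hads(rep(3, 7))$sub_score, 21L)
  expect_equal(as.character(score_hads(rep(3, 7))$hads_class), "case")
  r <- score_hads(c(1, 1, 1, 1, 1, 1, 2))
  expect_identical(r$sub_score, 8L)
  expect_equal(as.character(r$hads_class), "borderline")
})

test_that("HADS scoring validates items and is permutation-invariant", {
  expect_error(score_hads(rep(1, 6)), "exactly 7")
  expect_error(score_hads(c(rep(1, 6), 4)), "0..3")
  expect_error(score_hads(c(rep(1, 6), -1)), "0..3")
  expect_error(score_hads(c(rep(1, 6), 1.5)), "0..3")
  set.seed(11)
  items <- c(0, 3, 2, 1, 1, 0, 2)
  base <- score_hads(items)
  for (i in 1:10) {
    perm <- sample(items)
    expect_identical(score_hads(perm)$sub_score, base$sub_score)
    expect_identical(score_hads(perm)$hads_class, base$hads_class)
  }
})

test_that("score_subjects appends FIS and HADS columns to a table", {
  df <- data.frame(sa = c(0, 490.5), sp = c(0, 110), acd = c(0, 12.08))
  for (i in 1:7) df[[paste0("hads_", i)]] <- c(0, 2)
  out <- score_subjects(df)
  expect_equal(out$fis_raw, c(4.458, 12.45354), tolerance = 1e-10)
  expect_identical(out$hads_sub_score, c(0L, 14L))
  expect_equal(as.character(out$hads_class), c("normal", "case"))
})
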