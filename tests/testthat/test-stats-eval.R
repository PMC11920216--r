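test_that("roc_auc matches hand-computed examples", {
  # pos {2,3}, neg {1,4}: 2 of 4 pairs concordant
  expect_equal(roc_auc(c(2, 3, 1, 4), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  # perfect separation: auc 1, Hanley-McNeil se 0
  r <- roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)
  # constant (degenerate) score: no discrimination
  expect_equal(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("roc_auc equals the O(n^2) Mann-Whitney count (property)", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    is_pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:10, n, replace = TRUE)   # many ties
    expect_equal(roc_auc(scores, is_pos)$auc, pairwise_auc(scores, is_pos))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(40)
  is_pos <- rep(c(TRUE, FALSE), 20)
  a0 <- roc_auc(scores, is_pos)$auc
  expect_equal(roc_auc(exp(scores), is_pos)$auc, a0)
  expect_equal(roc_auc(3 * scores - 7, is_pos)$auc, a0)
  expect_equal(roc_auc(atan(scores), is_pos)$auc, a0)
})

test_that("roc_auc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- rnorm(60)
  is_pos <- rep(c(TRUE, FALSE), 30)
  ours <- roc_auc(scores, is_pos)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = is_pos, predictor = scores, quiet = TRUE,
    direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(ours, ref)
})

test_that("youden_cutoff matches examples and the brute-force scan", {
  co <- youden_cutoff(c(1, 2, 3, 4, 5, 6),
                      c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(co$youden_j, 1)
  expect_equal(co$threshold, 3.5)
  co2 <- youden_cutoff(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(co2$youden_j, 0.5)
  co3 <- youden_cutoff(rep(1, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(co3$youden_j, 0)
  set.seed(77)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 5, 0.5), n, replace = TRUE)
    is_pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    co <- youden_cutoff(scores, is_pos)
    expect_equal(co$youden_j, brute_youden(scores, is_pos))
    expect_gte(co$youden_j, -1); expect_lte(co$youden_j, 1)
  }
})

test_that("youden ties break toward the lower threshold", {
  # J = 1 over a whole threshold interval; lowest candidate wins
  co <- youden_cutoff(c(1, 10), c(FALSE, TRUE))
  expect_equal(co$threshold, 5.5)  # single midpoint candidate
  # plateau created by a gap in scores with an interior tie
  co2 <- youden_cutoff(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(co2$threshold, 5)   # midpoint of 2 and 8
})

test_that("delong_compare satisfies its algebraic identities", {
  set.seed(9)
  s <- rnorm(20); is_pos <- rep(c(TRUE, FALSE), 10)
  same <- delong_compare(s, s, is_pos)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  s2 <- rnorm(20) + is_pos
  dl <- delong_compare(s, s2, is_pos)
  expect_equal(dl$auc_a, roc_auc(s, is_pos)$auc)
  expect_equal(dl$auc_b, roc_auc(s2, is_pos)$auc)
  expect_gte(dl$p, 0); expect_lte(dl$p, 1)
  expect_error(delong_compare(s, s2[-1], is_pos), "equal length")
})

test_that("delong variance equals the brute-force grouped jackknife", {
  naive_auc <- function(x, y) pairwise_auc(c(x, y),
                                           rep(c(TRUE, FALSE), c(length(x), length(y))))
  set.seed(15)
  for (i in 1:5) {
    m <- sample(4:8, 1); n <- sample(4:8, 1)
    pos_a <- rnorm(m, 1); neg_a <- rnorm(n)
    pos_b <- pos_a + rnorm(m, 0, 0.7); neg_b <- neg_a + rnorm(n, 0, 0.7)
    is_pos <- rep(c(TRUE, FALSE), c(m, n))
    dl <- delong_compare(c(pos_a, neg_a), c(pos_b, neg_b), is_pos)
    dfun <- function(ia, ina)
      naive_auc(pos_a[ia], neg_a[ina]) - naive_auc(pos_b[ia], neg_b[ina])
    dp <- vapply(1:m, function(k) dfun(setdiff(1:m, k), 1:n), numeric(1))
    dn <- vapply(1:n, function(k) dfun(1:m, setdiff(1:n, k)), numeric(1))
    jk <- (m - 1) / m * sum((dp - mean(dp))^2) +
      (n - 1) / n * sum((dn - mean(dn))^2)
    expect_equal(dl$se_delta^2, jk, tolerance = 1e-12)
  }
})

test_that("delong_compare agrees with pROC's paired roc.test", {
  skip_if_not_installed("pROC")
  set.seed(23)
  is_pos <- rep(c(TRUE, FALSE), c(15, 15))
  sa <- rnorm(30) + is_pos
  sb <- rnorm(30) + 0.5 * is_pos
  dl <- delong_compare(sa, sb, is_pos)
  ra <- pROC::roc(is_pos, sa, quiet = TRUE, direction = "<",
                  levels = c(FALSE, TRUE))
  rb <- pROC::roc(is_pos, sb, quiet = TRUE, direction = "<",
                  levels = c(FALSE, TRUE))
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(dl$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
  expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("stratified split preserves proportions and partitions", {
  labels <- rep(c("a", "b", "c"), c(30, 20, 10))
  parts <- stratified_split(labels, split_spec(0.7, seed = 3))
  expect_identical(sort(c(parts$train, parts$test)), 1:60)
  for (lv in c("a", "b", "c")) {
    n_tr <- sum(labels[parts$train] == lv)
    expect_lte(abs(n_tr - 0.7 * sum(labels == lv)), 1)
  }
})

test_that("margin classifier separates a separable scalar feature", {
  set.seed(2)
  x <- c(rnorm(40, 0), rnorm(40, 10))
  y <- rep(c(FALSE, TRUE), each = 40)
  clf <- train_margin_classifier(x, y, split_spec(0.7, seed = 1))
  sc <- clf$score(x[clf$test])
  expect_equal(mean((sc > 0) == y[clf$test]), 1)  # perfect test accuracy
  expect_equal(roc_auc(sc, y[clf$test])$auc, 1)
  # monotone orientation: higher feature -> higher score
  expect_true(all(diff(clf$score(seq(0, 10, 1))) > 0))
})

test_that("margin classifier scores are chance-level for independent labels", {
  set.seed(4)
  n <- 2000
  x <- rnorm(n)
  y <- sample(c(TRUE, FALSE), n, replace = TRUE)
  clf <- train_margin_classifier(x, y, split_spec(0.7, seed = 8))
  a <- roc_auc(clf$score(x[clf$test]), y[clf$test])$auc
  expect_lt(abs(a - 0.5), 0.05)
  expect_error(train_margin_classifier(x, rep(TRUE, n)), "single class")
})

test_that("one-vs-one AUC is 1 for ordered classes, 0.5 for shuffled", {
  set.seed(6)
  labels <- factor(rep(anxiety_levels(), each = 60),
                   levels = anxiety_levels())
  feature <- rep(c(0, 10, 20), each = 60) + rnorm(180, 0, 0.5)
  res <- one_vs_one_auc(feature, labels, split_spec(0.7, seed = 2))
  expect_equal(res$macro_auc, 1)
  expect_true(all(res$pairs$auc == 1))

  set.seed(60)
  labels2 <- factor(rep(anxiety_levels(), each = 300),
                    levels = anxiety_levels())
  feat2 <- rnorm(900)
  res2 <- one_vs_one_auc(feat2, labels2, split_spec(0.7, seed = 2))
  expect_lt(abs(res2$macro_auc - 0.5), 0.05)
})

test_that("identical class distributions give a chance-level pair", {
  set.seed(8)
  labels <- factor(rep(anxiety_levels(), each = 150),
                   levels = anxiety_levels())
  # normal and borderline share one distribution; case is far away
  feature <- c(rnorm(150), rnorm(150), rnorm(150, 30))
  res <- one_vs_one_auc(feature, labels, split_spec(0.7, seed = 5))
  pm <- res$pair_mean
  same <- pm$mean_auc[pm$pair == "normal vs borderline"]
  far <- pm$mean_auc[pm$pair == "normal vs case"]
  expect_lt(abs(same - 0.5), 0.12)
  expect_gt(far, 0.99)
})

test_that("spearman_matrix handles identities, sign and constants", {
  set.seed(12)
  x <- rnorm(30)
  df <- data.frame(x = x, neg = -x, noise = rnorm(30), k = rep(1, 30))
  sp <- spearman_matrix(df)
  expect_equal(unname(sp$r["x", "x"]), 1)
  expect_equal(unname(sp$r["x", "neg"]), -1)
  expect_true(all(is.na(sp$r["k", ])))        # constant column undefined
  expect_true(is.na(sp$r_filtered["x", "noise"]) ||
                sp$p["x", "noise"] <= 0.05)
  expect_equal(unname(sp$r_filtered["x", "neg"]), -1)
  expect_identical(sp$r, t(sp$r))
  expect_error(spearman_matrix(df[1:2, ]), "at least 3")
})

test_that("evaluate_all produces a coherent report on a synthetic cohort", {
  tab <- score_subjects(cohort_table(
    sample_cohort(synthetic_config(n_per_class = 40, seed = 19))))
  rep <- evaluate_all(tab, split_spec(0.7, seed = 4))
  expect_named(rep$macro_auc, c("sa", "sp", "acd", "fis"))
  expect_true(all(rep$macro_auc >= 0 & rep$macro_auc <= 1))
  expect_identical(nrow(rep$delong), 18L)   # 6 feature pairs x 3 class pairs
  expect_true(all(rep$delong$p >= 0 & rep$delong$p <= 1))
  co <- rep$cutoffs$normal_vs_borderline
  expect_gte(co$youden_j, 0)
  # separable toy cohort: cutoffs sit between the class score ranges
  toy <- data.frame(sa = 0, sp = 0,
                    acd = rep(c(10, 100, 250), each = 20),
                    hads_class = factor(rep(anxiety_levels(), each = 20),
                                        levels = anxiety_levels()))
  toy$fis_raw <- 4.458 + 0.213 * toy$acd
  toy$sa <- toy$acd + rnorm(60, 0, 1)
  toy$sp <- toy$acd + rnorm(60, 0, 1)
  rep2 <- evaluate_all(toy, split_spec(0.7, seed = 6))
  th <- rep2$cutoffs$normal_vs_borderline$threshold
  expect_gt(th, max(toy$fis_raw[toy$hads_class == "normal"]))
  expect_lt(th, min(toy$fis_raw[toy$hads_class == "borderline"]))
  # degenerate cohort errors clearly
  bad <- toy; bad$hads_class <- factor("normal", levels = anxiety_levels())
  expect_error(evaluate_all(bad), "three anxiety classes")
})
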