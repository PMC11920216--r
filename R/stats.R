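#' ROC area under the curve with Wilcoxon-equivalence standard error
#'
#' The AUC is computed through its equivalence to the Mann-Whitney U
#' statistic: the proportion of (positive, negative) score pairs in which
#' the positive scores higher, ties counting one half (midrank form). The
#' standard error uses the Hanley-McNeil formula with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' A degenerate, constant score yields AUC 0.5 (no discrimination).
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels vector of two classes (logical, factor or character).
#' @param positive which label is the positive class; defaults to `TRUE`
#'   for logicals, else the last factor level / alphabetically larger value.
#' @return object of class `auc_estimate`: list with `auc`, `se`,
#'   `positive_class`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(2, 3, 1, 4), c(TRUE, TRUE, FALSE, FALSE))  # auc 0.5
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  b <- as_binary(labels, positive)
  if (length(scores) != length(b$is_pos))
    stop("`scores` and `labels` lengths differ")
  if (any(!is.finite(scores))) stop("scores must be finite")
  m <- sum(b$is_pos); n <- sum(!b$is_pos)
  if (m == 0 || n == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[b$is_pos]) - m * (m + 1) / 2) / (m * n)
  a <- auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt(max(0, a * (1 - a) + (m - 1) * (q1 - a^2) +
                   (n - 1) * (q2 - a^2)) / (m * n))
  structure(list(auc = auc, se = se, positive_class = b$positive,
                 n_pos = m, n_neg = n),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f +/- %.3f (positive: %s; %d pos / %d neg)\n",
              x$auc, x$se, x$positive_class, x$n_pos, x$n_neg))
  invisible(x)
}

# normalize two-class labels to logical + positive label name
as_binary <- function(labels, positive = NULL) {
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(as.character(labels)))
  if (is.logical(labels)) {
    positive <- if (is.null(positive)) TRUE else positive
    return(list(is_pos = labels == positive,
                positive = as.character(positive)))
  }
  if (length(lv) != 2)
    stop("labels must contain exactly two classes, got ", length(lv))
  if (is.null(positive)) positive <- lv[2]
  positive <- as.character(positive)
  if (!positive %in% lv) stop("positive class '", positive, "' not in labels")
  list(is_pos = as.character(labels) == positive, positive = positive)
}

#' ROC curve coordinates
#'
#' Sensitivity / specificity swept over all distinct score thresholds
#' (rule: positive when score > threshold), for plotting and export.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `sensitivity`, `specificity`, `fpr`.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  b <- as_binary(labels, positive)
  th <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(th, function(t) mean(scores[b$is_pos] > t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!b$is_pos] <= t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec,
             fpr = 1 - spec)
}

#' Stratified train/test split specification
#'
#' @param train_fraction fraction of subjects assigned to training
#'   (default 0.70, tested on the remaining 30%).
#' @param seed integer seed for the random split.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified split of labels into train and test indices
#'
#' Samples `train_fraction` of each class (rounded) into the training
#' partition; train and test are disjoint and exhaustive, and class
#' proportions are preserved to within one subject per class.
#'
#' @param labels class labels (any number of classes).
#' @param split a [split_spec()].
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, split = split_spec()) {
  set.seed(split$seed)
  train <- integer(0)
  for (lv in unique(as.character(labels))) {
    idx <- which(as.character(labels) == lv)
    k <- round(split$train_fraction * length(idx))
    k <- min(max(k, 1L), length(idx) - 1L)   # keep both partitions non-empty
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train a maximum-margin classifier on a single scalar feature
#'
#' Fits a soft-margin linear support vector machine on the standardized
#' feature over the training partition and returns a monotone decision
#' score oriented so that larger values indicate the positive class.
#' For a single scalar feature a linear margin is a threshold rule; the
#' decision score is an affine function of the feature.
#'
#' @param feature numeric per-subject scalar feature.
#' @param labels binary labels.
#' @param split a [split_spec()]; the classifier is fitted on the stratified
#'   training partition.
#' @param positive positive class (see [roc_auc()]).
#' @param cost soft-margin cost parameter.
#' @return object of class `margin_classifier` with `$score(x)` (the
#'   decision function), `$train`, `$test` index vectors and the fitted
#'   `$model`.
#' @export
train_margin_classifier <- function(feature, labels, split = split_spec(),
                                    positive = NULL, cost = 1) {
  b <- as_binary(labels, positive)
  stopifnot(length(feature) == length(b$is_pos))
  parts <- stratified_split(b$is_pos, split)
  ytr <- b$is_pos[parts$train]
  if (length(unique(ytr)) < 2)
    stop("training partition contains a single class")
  xtr <- feature[parts$train]
  mu <- mean(xtr); sdev <- stats::sd(xtr)
  if (sdev == 0) stop("feature is constant on the training partition")
  fit <- e1071::svm(x = matrix((xtr - mu) / sdev, ncol = 1),
                    y = factor(ytr, levels = c(FALSE, TRUE)),
                    kernel = "linear", cost = cost, scale = FALSE)
  score1 <- function(x) {
    z <- matrix((x - mu) / sdev, ncol = 1)
    as.numeric(attr(stats::predict(fit, z, decision.values = TRUE),
                    "decision.values"))
  }
  # orient the decision score toward the positive class
  flip <- mean(score1(xtr[ytr])) < mean(score1(xtr[!ytr]))
  score <- if (flip) function(x) -score1(x) else score1
  structure(list(score = score, model = fit, train = parts$train,
                 test = parts$test, positive_class = b$positive,
                 mu = mu, sd = sdev),
            class = "margin_classifier")
}

#' One-vs-one multiclass AUC for a scalar feature
#'
#' For each unordered pair of classes, a binary maximum-margin classifier
#' is trained on the training partition of the pair's subjects and its test
#' scores are evaluated by ROC AUC with each class of the pair in turn as
#' the positive class. The macro-mean AUC averages the pair-level AUCs.
#'
#' @param feature numeric per-subject scalar.
#' @param labels labels with three (or more) classes.
#' @param split a [split_spec()]; the split is stratified over all classes
#'   once, so different features share the same partitions.
#' @return list with `pairs` (data.frame: class_a, class_b, positive, auc,
#'   se, n_pos, n_neg), `pair_mean` (data.frame per pair), `macro_auc`,
#'   and `test_scores` (list per pair: scores, labels, test indices) for
#'   downstream paired comparisons.
#' @export
one_vs_one_auc <- function(feature, labels, split = split_spec()) {
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  if (length(lv) < 3) stop("one-vs-one evaluation expects >= 3 classes")
  if (!all(lv %in% unique(as.character(labels))))
    stop("every class must be present")
  parts <- stratified_split(labels, split)

  combs <- utils::combn(lv, 2)
  rows <- list(); means <- list(); tscores <- list()
  for (k in seq_len(ncol(combs))) {
    a <- combs[1, k]; bcl <- combs[2, k]
    sel_tr <- parts$train[as.character(labels[parts$train]) %in% c(a, bcl)]
    sel_te <- parts$test[as.character(labels[parts$test]) %in% c(a, bcl)]
    y_tr <- as.character(labels[sel_tr]) == bcl
    y_te <- as.character(labels[sel_te]) == bcl
    if (length(unique(y_tr)) < 2 || length(unique(y_te)) < 2)
      stop("class pair ", a, "/", bcl, " missing from a partition")
    x_tr <- feature[sel_tr]
    mu <- mean(x_tr); sdev <- stats::sd(x_tr)
    if (sdev == 0) stop("feature is constant on the training partition")
    fit <- e1071::svm(x = matrix((x_tr - mu) / sdev, ncol = 1),
                      y = factor(y_tr, levels = c(FALSE, TRUE)),
                      kernel = "linear", cost = 1, scale = FALSE)
    dec <- function(x) as.numeric(attr(
      stats::predict(fit, matrix((x - mu) / sdev, ncol = 1),
                     decision.values = TRUE), "decision.values"))
    flip <- mean(dec(x_tr[y_tr])) < mean(dec(x_tr[!y_tr]))
    sc_te <- if (flip) -dec(feature[sel_te]) else dec(feature[sel_te])

    auc_b <- roc_auc(sc_te, y_te, positive = TRUE)     # positive = class b
    auc_a <- roc_auc(-sc_te, !y_te, positive = TRUE)   # positive = class a
    pair_lab <- paste(a, "vs", bcl)
    rows[[length(rows) + 1]] <- data.frame(
      pair = pair_lab, class_a = a, class_b = bcl,
      positive = c(a, bcl), auc = c(auc_a$auc, auc_b$auc),
      se = c(auc_a$se, auc_b$se),
      n_pos = c(auc_a$n_pos, auc_b$n_pos),
      n_neg = c(auc_a$n_neg, auc_b$n_neg))
    means[[length(means) + 1]] <- data.frame(
      pair = pair_lab, mean_auc = mean(c(auc_a$auc, auc_b$auc)),
      se = mean(c(auc_a$se, auc_b$se)))
    tscores[[pair_lab]] <- list(scores = sc_te, labels = y_te,
                                positive = bcl, test_idx = sel_te)
  }
  pair_mean <- do.call(rbind, means)
  list(pairs = do.call(rbind, rows), pair_mean = pair_mean,
       macro_auc = mean(pair_mean$mean_auc), test_scores = tscores,
       split_idx = parts)
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' subjects, via DeLong's structural components of the Mann-Whitney kernel
#' `psi = 1 / 0.5 / 0` for greater / tie / less. For each score, `V10[i]`
#' is the mean kernel of positive subject i against all negatives and
#' `V01[j]` the symmetric negative-side component; the covariance matrix of
#' the two AUCs follows from the empirical covariances of these components,
#' and `z = (AUC_a - AUC_b) / SE` is referred to the standard normal
#' (two-sided p).
#'
#' Identical score vectors give a difference of exactly 0 and are reported
#' with `p = 1` and `degenerate = TRUE` (zero variance of the difference).
#'
#' @param scores_a,scores_b numeric vectors of paired scores (same
#'   subjects).
#' @param labels binary labels.
#' @param positive positive class.
#' @return object of class `delong_result`: `auc_a`, `auc_b`, `delta_auc`
#'   (absolute difference), `se_delta`, `z` (signed, for AUC_a - AUC_b),
#'   `p`, `ci95` (for the signed difference), `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  b <- as_binary(labels, positive)
  if (length(scores_a) != length(b$is_pos))
    stop("`labels` length differs from scores")
  if (!any(b$is_pos) || all(b$is_pos))
    stop("both classes must be present")
  if (sum(b$is_pos) < 2 || sum(!b$is_pos) < 2)
    stop("DeLong comparison needs at least 2 subjects per class")

  comp <- function(s) {
    x <- s[b$is_pos]; y <- s[!b$is_pos]
    psi <- outer(x, y, function(a, bb)
      (a > bb) + 0.5 * (a == bb))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  ca <- comp(scores_a); cb <- comp(scores_b)
  m <- sum(b$is_pos); n <- sum(!b$is_pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- ca$auc - cb$auc
  degenerate <- var_delta <= .Machine$double.eps
  if (degenerate) {
    z <- 0; p <- 1; se <- 0
  } else {
    se <- sqrt(var_delta)
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc,
                 delta_auc = abs(diff), se_delta = se, z = z, p = p,
                 ci95 = diff + c(-1, 1) * stats::qnorm(0.975) * se,
                 degenerate = degenerate),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(
    "DeLong: AUC %.3f vs %.3f, |dAUC| %.3f +/- %.3f, z %.2f, p %.4g%s\n",
    x$auc_a, x$auc_b, x$delta_auc, x$se_delta, x$z, x$p,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Scans all candidate thresholds -- midpoints between adjacent distinct
#' sorted scores, plus one below the minimum and one above the maximum --
#' and returns the threshold maximizing Youden's
#' `J = sensitivity + specificity - 1` for the rule "positive when
#' score > threshold". Ties are broken toward the lower threshold.
#'
#' @inheritParams roc_auc
#' @return object of class `cutoff_result`: `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels, positive = NULL) {
  b <- as_binary(labels, positive)
  if (!any(b$is_pos) || all(b$is_pos))
    stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) c(u - 1, u + 1) else
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(t) mean(scores[b$is_pos] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!b$is_pos] <= t), numeric(1))
  j <- sens + spec - 1
  k <- which.max(j)          # first maximum = lowest threshold
  structure(list(threshold = cand[k], youden_j = j[k],
                 sensitivity = sens[k], specificity = spec[k]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden J %.3f at threshold %g (sens %.3f, spec %.3f)\n",
              x$youden_j, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Spearman rank-correlation matrix with significance filter
#'
#' Pairwise Spearman correlations (tie-corrected midranks) between all
#' numeric columns, with two-sided p-values and a filtered copy in which
#' entries with `p > alpha` are masked (`NA`). Constant columns yield
#' undefined (masked) correlations rather than an error.
#'
#' @param table data.frame of per-subject numeric columns.
#' @param alpha significance level for the filtered matrix (default 0.05).
#' @return list with symmetric matrices `r`, `p`, `r_filtered`.
#' @export
spearman_matrix <- function(table, alpha = 0.05) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 subjects")
  if (ncol(num) < 2) stop("need at least 2 numeric columns")
  k <- ncol(num)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- num[[i]]; y <- num[[j]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, masked
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  rf <- r
  rf[is.na(p) | p > alpha] <- NA_real_
  list(r = r, p = p, r_filtered = rf)
}

#' Run the full evaluation pipeline on a scored cohort
#'
#' Reproduces the evaluation battery on a per-subject table: one-vs-one AUC
#' for each of the four features (SA, SP, ACD, FIS) against the HADS class,
#' DeLong paired comparisons of all six feature pairs within each class
#' pair, and Youden cutoffs on FIS for normal-vs-borderline and
#' borderline-vs-case.
#'
#' All four features share one stratified 70/30 split, so the test scores
#' are paired across features as the DeLong comparison requires.
#'
#' @param df data.frame with columns `sa`, `sp`, `acd`, `fis_raw` and
#'   `hads_class` (three-level factor).
#' @param split a [split_spec()].
#' @return object of class `fixstab_report`: list with `ovo` (per-feature
#'   one-vs-one results), `macro_auc` (named vector), `delong` (data.frame),
#'   `cutoffs` (list), `split`.
#' @export
evaluate_all <- function(df, split = split_spec()) {
  need <- c("sa", "sp", "acd", "fis_raw", "hads_class")
  if (!all(need %in% names(df)))
    stop("cohort table must contain columns: ", paste(need, collapse = ", "))
  if (nlevels(droplevels(as.factor(df$hads_class))) < 3)
    stop("all three anxiety classes must be present")
  features <- c(sa = "sa", sp = "sp", acd = "acd", fis = "fis_raw")

  ovo <- lapply(features, function(f)
    one_vs_one_auc(df[[f]], df$hads_class, split))
  macro <- vapply(ovo, `[[`, numeric(1), "macro_auc")

  # DeLong: every unordered feature pair, within every class pair,
  # on the shared test-partition scores
  pair_names <- names(ovo[[1]]$test_scores)
  fp <- utils::combn(names(features), 2)
  dl <- list()
  for (cp in pair_names) {
    for (k in seq_len(ncol(fp))) {
      fa <- fp[1, k]; fb <- fp[2, k]
      ta <- ovo[[fa]]$test_scores[[cp]]
      tb <- ovo[[fb]]$test_scores[[cp]]
      res <- delong_compare(ta$scores, tb$scores, ta$labels, positive = TRUE)
      dl[[length(dl) + 1]] <- data.frame(
        class_pair = cp, feature_a = toupper(fa), feature_b = toupper(fb),
        auc_a = res$auc_a, auc_b = res$auc_b, delta_auc = res$delta_auc,
        se = res$se_delta, z = res$z, p = res$p)
    }
  }
  delong <- do.call(rbind, dl)

  # Youden cutoffs on the FIS feature itself for adjacent class pairs
  cutoffs <- list()
  for (cp in list(c("normal", "borderline"), c("borderline", "case"))) {
    sel <- as.character(df$hads_class) %in% cp
    cutoffs[[paste(cp, collapse = "_vs_")]] <-
      youden_cutoff(df$fis_raw[sel],
                    as.character(df$hads_class)[sel] == cp[2],
                    positive = TRUE)
  }

  structure(list(ovo = ovo, macro_auc = macro, delong = delong,
                 cutoffs = cutoffs, split = split),
            class = "fixstab_report")
}

#' @export
print.fixstab_report <- function(x, ...) {
  cat("fixstab evaluation report\n")
  cat("  macro-mean one-vs-one AUC:\n")
  for (f in names(x$macro_auc))
    cat(sprintf("    %-4s %.3f\n", toupper(f), x$macro_auc[f]))
  for (nm in names(x$cutoffs)) {
    co <- x$cutoffs[[nm]]
    cat(sprintf("  FIS cutoff %s: threshold %.2f, J %.2f\n",
                gsub("_", " ", nm), co$threshold, co$youden_j))
  }
  cat(sprintf("  DeLong comparisons: %d rows\n", nrow(x$delong)))
  invisible(x)
}
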