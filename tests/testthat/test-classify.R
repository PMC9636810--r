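test_that("stratified_kfold balances classes and is seed-deterministic", {
  lab <- rep(c(1, 0), each = 10)
  f <- stratified_kfold(lab, k = 5, seed = 1)
  for (fold in 1:5) {
    expect_equal(sum(f == fold & lab == 1), 2)
    expect_equal(sum(f == fold & lab == 0), 2)
  }

  # 7 positives over 5 folds: counts {2,2,1,1,1} in some order
  lab2 <- c(rep(1, 7), rep(0, 10))
  f2 <- stratified_kfold(lab2, k = 5, seed = 2)
  expect_equal(sort(as.numeric(table(factor(f2[lab2 == 1], levels = 1:5)))),
               c(1, 1, 1, 2, 2))

  expect_identical(stratified_kfold(lab2, 5, seed = 7),
                   stratified_kfold(lab2, 5, seed = 7))
  expect_false(identical(stratified_kfold(lab2, 5, seed = 7),
                         stratified_kfold(lab2, 5, seed = 8)))
  expect_error(stratified_kfold(c(1, 1, 0, 0, 0, 0, 0), k = 5), "fewer than k")

  # general stratification property across random label mixes
  set.seed(30)
  for (rep in 1:10) {
    n1 <- sample(6:40, 1); n0 <- sample(6:40, 1)
    lab3 <- sample(c(rep(1, n1), rep(0, n0)))
    f3 <- stratified_kfold(lab3, k = 5, seed = rep)
    for (cl in c(0, 1)) {
      counts <- table(factor(f3[lab3 == cl], levels = 1:5))
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("roc_auc equals the pair-counting oracle and is symmetric", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    sc <- sample(round(runif(n), 2))  # rounded scores force ties
    expect_equal(roc_auc(sc, lab), auc_pair_oracle(sc, lab))
    # complement symmetry: AUC(s, y) + AUC(s, 1 - y) = 1
    expect_equal(roc_auc(sc, lab) + roc_auc(sc, 1 - lab), 1)
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:5) {
    lab <- c(rep(1, 30), rep(0, 40))
    sc <- rnorm(70) + lab
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
  }
})

test_that("auc_ci brackets the point estimate and is seed-stable", {
  set.seed(4)
  lab <- c(rep(1, 25), rep(0, 25))
  sc <- rnorm(50) + 1.2 * lab
  ci <- auc_ci(sc, lab, B = 500, seed = 10)
  point <- roc_auc(sc, lab)
  expect_lte(ci[["low"]], point + 1e-9)
  expect_gte(ci[["high"]], point - 1e-9)
  expect_identical(auc_ci(sc, lab, B = 500, seed = 10), ci)
  expect_error(auc_ci(sc, lab, B = 50), ">= 100")

  # perfect separation: upper bound reaches 1
  sc2 <- lab + 0.1
  expect_equal(auc_ci(sc2, lab, B = 200, seed = 1)[["high"]], 1)
})

test_that("confusion metrics and kappa match exhaustive small-table arithmetic", {
  # hand case: TP 40, FN 10, FP 20, TN 30
  v <- vectors_from_counts(40, 10, 20, 30)
  cm <- confusion_metrics(v$scores, v$labels)
  expect_equal(cm[["sensitivity"]], 0.8)
  expect_equal(cm[["specificity"]], 0.6)
  expect_equal(cm[["precision"]], 2 / 3)
  expect_equal(cm[["f1"]], 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8))
  expect_equal(cm[["balanced_accuracy"]], 0.7)
  expect_equal(cohens_kappa(as.integer(v$scores >= 0.5), v$labels), 0.4)

  # all tables with n <= 12 and both classes present
  for (n in 2:12) {
    parts <- expand.grid(tp = 0:n, fn = 0:n, fp = 0:n)
    parts$tn <- n - parts$tp - parts$fn - parts$fp
    parts <- parts[parts$tn >= 0 & (parts$tp + parts$fn) > 0 &
                     (parts$fp + parts$tn) > 0, ]
    for (r in seq_len(nrow(parts))) {
      tp <- parts$tp[r]; fn <- parts$fn[r]; fp <- parts$fp[r]; tn <- parts$tn[r]
      v <- vectors_from_counts(tp, fn, fp, tn)
      cm <- confusion_metrics(v$scores, v$labels)
      ref <- metrics_from_counts(tp, fn, fp, tn)
      for (f in names(ref))
        expect_equal(unname(cm[[f]]), ref[[f]], info = sprintf(
          "%s at table (%d,%d,%d,%d)", f, tp, fn, fp, tn))
      expect_equal(cohens_kappa(as.integer(v$scores >= 0.5), v$labels),
                   kappa_from_counts(tp, fn, fp, tn),
                   info = sprintf("kappa at (%d,%d,%d,%d)", tp, fn, fp, tn))
    }
  }
})

test_that("degenerate predictions are flagged, not silently zeroed", {
  lab <- c(1, 1, 0, 0)
  cm <- confusion_metrics(c(0.9, 0.9, 0.9, 0.9), lab)  # all predicted positive
  expect_equal(cm[["sensitivity"]], 1)
  expect_equal(cm[["specificity"]], 0)
  cm2 <- confusion_metrics(c(0.1, 0.1, 0.1, 0.1), lab)  # none predicted positive
  expect_true(is.na(cm2[["precision"]]))
  expect_true("precision" %in% attr(cm2, "undefined"))
  expect_identical(cohens_kappa(c(1, 1), c(1, 1)), structure(
    NA_real_, undefined = "expected agreement is 1"))
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
})

test_that("kappa is near zero for label-permuted predictions", {
  set.seed(12)
  kaps <- vapply(1:200, function(i) {
    lab <- sample(c(rep(1, 20), rep(0, 20)))
    cohens_kappa(sample(lab), lab)
  }, numeric(1))
  expect_lt(abs(mean(kaps)), 3 * sd(kaps) / sqrt(length(kaps)))
})

test_that("baseline classifier separates separable data and not permuted labels", {
  # perfectly separated 1-D feature: training AUC 1
  x <- matrix(c(rnorm(20, 3), rnorm(20, -3)), ncol = 1)
  y <- c(rep(1, 20), rep(0, 20))
  m <- fit_baseline(x, y, l2 = 1e-3)
  expect_equal(roc_auc(predict(m, x), y), 1)
  expect_true(all(is.finite(m$weights)))

  # deterministic refit
  m2 <- fit_baseline(x, y, l2 = 1e-3)
  expect_identical(m$weights, m2$weights)

  expect_error(fit_baseline(x, rep(1, 40)), "both classes")

  # null calibration: permuted labels give CV AUC compatible with 0.5
  set.seed(33)
  xx <- matrix(rnorm(60 * 3), 60, 3)
  aucs <- vapply(1:12, function(s) {
    yy <- sample(c(rep(1, 30), rep(0, 30)))
    cross_validate(xx, yy, k = 5, seed = s, ci_B = 100)$mean[["auc"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)))
})

test_that("baseline matches an unpenalised GLM when the penalty vanishes", {
  set.seed(18)
  x <- matrix(rnorm(80 * 2), 80, 2)
  y <- as.integer(runif(80) < plogis(0.8 * x[, 1] - 0.5 * x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  m <- fit_baseline(x, y, l2 = 0, tol = 1e-10)
  z <- scale(x)
  g <- glm(y ~ z, family = binomial())
  expect_equal(unname(m$weights), unname(coef(g)[2:3]), tolerance = 1e-4)
  expect_equal(m$intercept, unname(coef(g)[1]), tolerance = 1e-4)
})

test_that("cross_validate produces the eight metrics with sane extremes", {
  set.seed(40)
  y <- c(rep(1, 15), rep(0, 20))
  x <- matrix(rnorm(35 * 2), 35, 2)

  # oracle scorer: score equals the label
  rep_o <- cross_validate(x, y, classifier = function(xtr, ytr, xte, idx)
    y[idx], k = 5, seed = 3, ci_B = 100)
  expect_equal(rep_o$mean[["auc"]], 1)
  expect_equal(rep_o$mean[["kappa"]], 1)
  expect_equal(nrow(rep_o$folds), 5)

  # constant scorer: AUC 0.5 and flagged-null precision per fold
  rep_c <- cross_validate(x, y, classifier = function(xtr, ytr, xte, idx)
    rep(0.2, length(idx)), k = 5, seed = 3, ci_B = 100)
  expect_equal(rep_c$mean[["auc"]], 0.5)
  expect_true(all(is.na(rep_c$folds$precision)))

  # precomputed external scores plug into the same harness
  sc <- y + rnorm(35, 0, 0.4)
  rep_p <- cross_validate(x, y, classifier = precomputed_classifier(sc),
                          k = 5, seed = 3, ci_B = 100)
  expect_gt(rep_p$mean[["auc"]], 0.8)
  expect_named(rep_p$mean, c("auc", "auc_ci_low", "auc_ci_high",
                             "balanced_accuracy", "precision", "recall", "f1",
                             "sensitivity", "specificity", "kappa"))
})
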