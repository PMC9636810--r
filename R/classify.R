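# Binary labels are handled as: positive class = "angle_closure" when labels
# are characters/factors containing it, otherwise the larger of the two
# label values (1 in 0/1, TRUE in logicals).
as_binary_labels <- function(labels, positive = NULL) {
  lab <- as.character(labels)
  levs <- unique(lab)
  if (length(levs) < 2L) stop_invalid("both classes must be present")
  if (length(levs) > 2L) stop_invalid("labels must be binary")
  if (is.null(positive)) {
    num <- suppressWarnings(as.numeric(levs))
    positive <- if ("angle_closure" %in% levs) "angle_closure"
                else if (!anyNA(num)) levs[which.max(num)]
                else sort(levs)[2]
  }
  if (!positive %in% levs) stop_invalid("positive class '%s' not present", positive)
  structure(as.integer(lab == positive), positive = positive)
}

#' Stratified k-fold assignment
#'
#' Shuffles sample indices within each class (reproducibly from `seed`) and
#' deals them round-robin into `k` folds, so per-fold class counts deviate
#' from perfect stratification by at most one sample.
#'
#' @param labels Class labels (binary or multi-class).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `fold_split`: integer vector of fold assignments in `1..k` with
#'   attributes `k` and `seed`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  if (!is_scalar_number(k) || k < 2 || k != round(k))
    stop_invalid("`k` must be an integer >= 2")
  k <- as.integer(k)
  lab <- as.character(labels)
  n <- length(lab)
  counts <- table(lab)
  if (any(counts < k))
    stop_invalid("class '%s' has %d members, fewer than k = %d",
                 names(counts)[which.min(counts)], min(counts), k)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(lab == cl))
      start <- sample.int(k, 1L)  # random dealing offset per class
      folds[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
    }
  })
  structure(folds, k = k, seed = as.integer(seed), class = "fold_split")
}

#' Ridge-regularised logistic baseline classifier
#'
#' A desk-scale stand-in classifier on the five kinematic features: features
#' are standardised on the training data, then a logistic model with L2
#' penalty is fitted by full-batch gradient descent to a fixed gradient
#' tolerance. It exists to exercise the evaluation harness; any external
#' scorer (e.g. exported per-video scores of a deep temporal network) can be
#' plugged into [cross_validate()] instead.
#'
#' @param x Numeric feature matrix (rows = videos).
#' @param y Labels (see [roc_auc()] for the positive-class convention).
#' @param l2 L2 penalty strength on the weights (not the intercept).
#' @param max_iter,tol Gradient-descent iteration cap and max-abs-gradient
#'   stopping tolerance.
#' @param seed Recorded for provenance; the fit itself is deterministic
#'   (zero initialisation).
#' @return A `baseline_model` with standardisation constants, weights,
#'   intercept and the training trace (iterations, final gradient norm).
#' @export
fit_baseline <- function(x, y, l2 = 1e-2, max_iter = 20000L, tol = 1e-8,
                         seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  yb <- as_binary_labels(y)
  if (nrow(x) != length(yb)) stop_invalid("`x` and `y` sizes differ")
  if (anyNA(x)) stop_invalid("missing feature values are not supported")
  if (min(table(yb)) < 2L) stop_invalid("need >= 2 samples per class to train")
  if (l2 < 0) stop_invalid("`l2` must be >= 0")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1  # constant features carry no information; leave unscaled
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  n <- nrow(z); p <- ncol(z)
  # step size from the Lipschitz constant of the mean logistic loss
  L <- 0.25 * max(eigen(crossprod(cbind(1, z)) / n, symmetric = TRUE,
                        only.values = TRUE)$values) + l2
  step <- 1 / L
  w <- numeric(p); b <- 0
  it <- 0L; gmax <- Inf
  while (it < max_iter) {
    eta <- drop(z %*% w) + b
    mu <- stats::plogis(eta)
    gw <- drop(crossprod(z, mu - yb)) / n + l2 * w
    gb <- mean(mu - yb)
    gmax <- max(abs(c(gw, gb)))
    if (gmax < tol) break
    w <- w - step * gw
    b <- b - step * gb
    it <- it + 1L
  }
  structure(list(center = ctr, scale = scl, weights = w, intercept = b,
                 l2 = l2, positive = attr(yb, "positive"),
                 trace = list(iterations = it, grad_max = gmax, seed = seed)),
            class = "baseline_model")
}

#' @rdname fit_baseline
#' @param object A `baseline_model`.
#' @param newdata Feature matrix to score.
#' @param ... Unused.
#' @return `predict()` returns scores in (0, 1): the predicted probability of
#'   the positive class.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  stats::plogis(drop(z %*% object$weights) + object$intercept)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Ridge-logistic baseline (l2 = %g, %d GD iterations, max|grad| %.2g)\n",
              x$l2, x$trace$iterations, x$trace$grad_max))
  cat("  weights:", paste(sprintf("%.4f", x$weights), collapse = " "),
      sprintf(" intercept: %.4f\n", x$intercept))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted one half. Uses midranks, equivalent to pair counting.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels; the positive class is `"angle_closure"` when
#'   present, otherwise the larger label value.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  yb <- as_binary_labels(labels)
  if (length(scores) != length(yb)) stop_invalid("`scores` and `labels` lengths differ")
  if (anyNA(scores)) stop_invalid("`scores` contains NA")
  n1 <- sum(yb == 1L); n0 <- sum(yb == 0L)
  r <- rank(scores)  # midranks
  (sum(r[yb == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified bootstrap percentile interval: positives and negatives are
#' resampled separately `B` times and the interval is taken from the
#' quantiles of the resampled AUCs.
#'
#' @inheritParams roc_auc
#' @param level Confidence level.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return Named numeric `c(low, high)` with attribute `auc` (point value).
#' @export
auc_ci <- function(scores, labels, level = 0.95, B = 2000L, seed = 1L) {
  if (!is_scalar_number(B) || B < 100) stop_invalid("`B` must be >= 100")
  yb <- as_binary_labels(labels)
  if (length(scores) != length(yb)) stop_invalid("`scores` and `labels` lengths differ")
  pos <- scores[yb == 1L]; neg <- scores[yb == 0L]
  n1 <- length(pos); n0 <- length(neg)
  point <- roc_auc(scores, labels)
  boots <- with_seed(seed, {
    vapply(seq_len(as.integer(B)), function(b) {
      p <- pos[sample.int(n1, n1, replace = TRUE)]
      ng <- neg[sample.int(n0, n0, replace = TRUE)]
      r <- rank(c(p, ng))
      (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(c(low = qs[1], high = qs[2]), auc = point, level = level)
}

#' Threshold-based confusion-matrix metrics
#'
#' Standard 2x2 definitions at a fixed operating threshold (`score >=
#' threshold` predicts the positive class): sensitivity (= recall),
#' specificity, precision, F1 and balanced accuracy
#' `(sensitivity + specificity) / 2`. Ratios with zero denominator (e.g.
#' precision with no positive predictions) are returned as `NA` and listed
#' in the `undefined` attribute rather than silently coerced to 0.
#'
#' @inheritParams roc_auc
#' @param threshold Operating threshold on the scores.
#' @return Named numeric vector with elements `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f1`, `balanced_accuracy`, `accuracy` (plain
#'   proportion correct), plus attribute `undefined`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  yb <- as_binary_labels(labels)
  if (length(scores) != length(yb)) stop_invalid("`scores` and `labels` lengths differ")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & yb == 1L); fn <- sum(pred == 0L & yb == 1L)
  fp <- sum(pred == 1L & yb == 0L); tn <- sum(pred == 0L & yb == 0L)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  bacc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  out <- c(sensitivity = sens, specificity = spec, precision = prec,
           recall = sens, f1 = f1, balanced_accuracy = bacc,
           accuracy = (tp + tn) / length(yb))
  structure(out, undefined = names(out)[is.na(out)],
            table = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement. When the expected agreement is 1
#' (both margins degenerate) kappa is undefined and returned as `NA`.
#'
#' @param predictions,labels Vectors of equal length (class labels or 0/1).
#' @return Kappa in `[-1, 1]`, or flagged `NA`.
#' @export
cohens_kappa <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop_invalid("`predictions` and `labels` lengths differ")
  p <- as.character(predictions); l <- as.character(labels)
  cats <- union(unique(p), unique(l))
  n <- length(p)
  po <- mean(p == l)
  pe <- sum(vapply(cats, function(cl) mean(p == cl) * mean(l == cl), numeric(1)))
  if (abs(1 - pe) < 1e-12)
    return(structure(NA_real_, undefined = "expected agreement is 1"))
  (po - pe) / (1 - pe)
}

#' Stratified cross-validated evaluation with the eight metrics
#'
#' Runs stratified k-fold cross-validation of a scoring classifier and
#' reports, per fold and as the across-fold mean, the eight evaluation
#' criteria: AUC (with stratified-bootstrap CI), balanced accuracy,
#' precision, recall, F1, sensitivity, specificity and Cohen's kappa.
#'
#' @param features Numeric feature matrix or data frame (rows = videos).
#' @param labels Binary labels.
#' @param classifier A function `f(x_train, y_train, x_test, idx_test)`
#'   returning numeric scores for the test rows. The default trains the
#'   ridge-logistic baseline per fold. Use [precomputed_classifier()] to
#'   evaluate scores exported from an external model (e.g. a deep temporal
#'   network) under the same harness.
#' @param k Number of folds.
#' @param seed Seed controlling the fold split and bootstrap.
#' @param threshold Operating threshold for the confusion-matrix metrics.
#' @param ci_B Bootstrap resamples for the per-fold AUC CI.
#' @param l2 Penalty passed to the default baseline classifier.
#' @return An `eval_report`: list with `folds` (per-fold data frame), `mean`
#'   (named means over folds), `threshold`, `k`, `seed`.
#' @export
cross_validate <- function(features, labels, classifier = NULL, k = 5,
                           seed = 1L, threshold = 0.5, ci_B = 2000L,
                           l2 = 1e-2) {
  x <- as.matrix(features)
  yb <- as_binary_labels(labels)
  if (is.null(classifier)) {
    classifier <- function(xtr, ytr, xte, idx) {
      predict(fit_baseline(xtr, ytr, l2 = l2), xte)
    }
  }
  folds <- stratified_kfold(yb, k = k, seed = seed)
  rows <- vector("list", attr(folds, "k"))
  for (f in seq_len(attr(folds, "k"))) {
    te <- which(folds == f); tr <- which(folds != f)
    sc <- classifier(x[tr, , drop = FALSE], yb[tr], x[te, , drop = FALSE], te)
    if (length(sc) != length(te)) stop_invalid("classifier returned %d scores for %d test rows",
                                               length(sc), length(te))
    auc <- roc_auc(sc, yb[te])
    ci <- auc_ci(sc, yb[te], B = ci_B, seed = seed + f)
    cm <- confusion_metrics(sc, yb[te], threshold = threshold)
    kap <- cohens_kappa(as.integer(sc >= threshold), yb[te])
    rows[[f]] <- data.frame(fold = f, n_test = length(te),
                            auc = auc, auc_ci_low = ci[["low"]],
                            auc_ci_high = ci[["high"]],
                            balanced_accuracy = cm[["balanced_accuracy"]],
                            precision = cm[["precision"]],
                            recall = cm[["recall"]], f1 = cm[["f1"]],
                            sensitivity = cm[["sensitivity"]],
                            specificity = cm[["specificity"]],
                            kappa = as.numeric(kap))
  }
  per_fold <- do.call(rbind, rows)
  means <- colMeans(per_fold[, setdiff(names(per_fold), c("fold", "n_test"))])
  structure(list(folds = per_fold, mean = means, threshold = threshold,
                 k = attr(folds, "k"), seed = seed),
            class = "eval_report")
}

#' Wrap externally computed scores as a cross-validation classifier
#'
#' @param scores Numeric vector of per-video scores aligned with the rows
#'   passed to [cross_validate()].
#' @return A classifier function for [cross_validate()] that ignores the
#'   training data and returns the stored scores of the test rows.
#' @export
precomputed_classifier <- function(scores) {
  force(scores)
  function(xtr, ytr, xte, idx) scores[idx]
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (seed %d, threshold %.2f)\n",
              x$k, x$seed, x$threshold))
  cat("Across-fold means:\n")
  print(round(x$mean, digits))
  invisible(x)
}
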