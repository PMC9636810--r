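#' Per-group summaries of the dynamic parameters
#'
#' @param values A data frame of per-video parameters (e.g. from
#'   [kinematics_table()]); every numeric column is summarised.
#' @param labels A vector of group labels, one per row; exactly two groups
#'   must be present.
#' @return A data frame with one row per parameter: `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator) per group.
#' @export
summarize_groups <- function(values, labels) {
  stopifnot(is.data.frame(values))
  if (length(labels) != nrow(values))
    stop_invalid("`labels` must have one entry per row of `values`")
  groups <- unique(as.character(labels))
  if (length(groups) < 2L)
    stop_invalid("both groups must be present; got only '%s'", groups[1])
  if (length(groups) > 2L) stop_invalid("more than two groups supplied")
  num <- names(values)[vapply(values, is.numeric, logical(1))]
  if (!length(num)) stop_invalid("no numeric parameter columns found")
  out <- do.call(rbind, lapply(num, function(p) {
    x1 <- values[[p]][labels == groups[1]]
    x2 <- values[[p]][labels == groups[2]]
    if (length(x1) < 2L || length(x2) < 2L)
      stop_invalid("each group needs at least 2 observations")
    data.frame(parameter = p,
               group1 = groups[1], n1 = length(x1), mean1 = mean(x1), sd1 = stats::sd(x1),
               group2 = groups[2], n2 = length(x2), mean2 = mean(x2), sd2 = stats::sd(x2))
  }))
  rownames(out) <- NULL
  out
}

pooled_sd <- function(s1, n1, s2, n2) {
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

check_summary_args <- function(m1, s1, n1, m2, s2, n2) {
  for (v in list(m1, s1, n1, m2, s2, n2))
    if (!is_scalar_number(v)) stop_invalid("summary statistics must be finite scalars")
  if (n1 < 2 || n2 < 2) stop_invalid("each group needs n >= 2")
  if (s1 < 0 || s2 < 0) stop_invalid("standard deviations must be >= 0")
  if (s1 == 0 && s2 == 0 && m1 == m2)
    stop_invalid("undefined statistic: both SDs are zero and the means are equal")
}

#' Independent-samples t-test from summary statistics
#'
#' Closed-form two-sample t-test from group means, SDs and sizes, either with
#' pooled variance (Student, `df = n1 + n2 - 2`) or the Welch-Satterthwaite
#' approximation. The p-value is two-sided.
#'
#' @param m1,s1,n1 Mean, sample SD and size of group 1.
#' @param m2,s2,n2 Mean, sample SD and size of group 2.
#' @param variant `"student_pooled"` (default) or `"welch"`.
#' @return An `irisdyn_ttest`: list with `t`, `df`, `p`, `variant`.
#' @examples
#' # the reference VPC_mean contrast: 0.4704 (0.1362, n 159) vs
#' # 0.5709 (0.1296, n 210) is significant far below 0.001
#' ttest_from_summary(0.4704, 0.1362, 159, 0.5709, 0.1296, 210)
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2,
                               variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  check_summary_args(m1, s1, n1, m2, s2, n2)
  if (variant == "student_pooled") {
    sp <- pooled_sd(s1, n1, s2, n2)
    if (sp == 0) stop_invalid("undefined statistic: pooled SD is zero")
    se <- sp * sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    if (se == 0) stop_invalid("undefined statistic: zero standard error")
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  structure(list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
                 variant = variant),
            class = "irisdyn_ttest")
}

#' Independent-samples t-test on raw samples
#'
#' Thin wrapper around [stats::t.test()] returning the same object type as
#' [ttest_from_summary()]; the two agree to numerical precision when applied
#' to the same data.
#'
#' @param x,y Numeric samples.
#' @inheritParams ttest_from_summary
#' @export
ttest_ind <- function(x, y, variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) stop_invalid("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
    stop_invalid("undefined statistic: both SDs are zero and the means are equal")
  tt <- stats::t.test(x, y, var.equal = (variant == "student_pooled"))
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, variant = variant),
            class = "irisdyn_ttest")
}

#' @export
print.irisdyn_ttest <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.4f, df = %.2f, p = %.3g\n",
              x$variant, x$t, x$df, x$p))
  invisible(x)
}

#' Post-hoc power of the two-sample t-test
#'
#' Observed (post-hoc) power at the realised effect size and sample sizes:
#' Cohen's `d = |m1 - m2| / pooled SD`, noncentrality
#' `ncp = d * sqrt(n1 n2 / (n1 + n2))`, and
#' `power = P(|T'| > t_crit)` under the noncentral t distribution with
#' `df = n1 + n2 - 2`.
#'
#' @inheritParams ttest_from_summary
#' @param alpha Significance level.
#' @param sided `"two"` (default) or `"one"`.
#' @return A `power_result`: list with `d`, `ncp`, `df`, `power`, `alpha`,
#'   `sided`.
#' @export
posthoc_power <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05,
                          sided = c("two", "one")) {
  sided <- match.arg(sided)
  check_summary_args(m1, s1, n1, m2, s2, n2)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid("`alpha` must be in (0, 1)")
  sp <- pooled_sd(s1, n1, s2, n2)
  if (sp == 0) stop_invalid("undefined effect size: pooled SD is zero")
  d <- abs(m1 - m2) / sp
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  if (sided == "two") {
    tcrit <- stats::qt(1 - alpha / 2, df)
    power <- 1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    power <- 1 - stats::pt(tcrit, df, ncp)
  }
  structure(list(d = d, ncp = ncp, df = df, power = power, alpha = alpha,
                 sided = sided),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Post-hoc power: d = %.4f, ncp = %.3f, df = %g, power = %.4f (alpha %.3g, %s-sided)\n",
              x$d, x$ncp, x$df, x$power, x$alpha, x$sided))
  invisible(x)
}

#' Group-comparison table of the dynamic parameters
#'
#' Builds the per-parameter comparison table: group means (SD), the
#' independent-samples t-test p-value and the post-hoc power, mirroring the
#' five-parameter comparison layout of the reference analysis.
#'
#' @inheritParams summarize_groups
#' @param parameters Columns to compare (default the five dynamic
#'   parameters present in `values`).
#' @inheritParams ttest_from_summary
#' @inheritParams posthoc_power
#' @return A data frame of class `group_stats` with per-parameter summary
#'   statistics, `t`, `df`, `p` and `power`.
#' @export
group_stats_table <- function(values, labels,
                              parameters = intersect(
                                c("vpc_mean", "vpc_max", "apc_max", "apc_mean",
                                  "apc_fitting"), names(values)),
                              variant = c("student_pooled", "welch"),
                              alpha = 0.05) {
  variant <- match.arg(variant)
  if (!length(parameters)) stop_invalid("no parameter columns to compare")
  summ <- summarize_groups(values[, parameters, drop = FALSE], labels)
  summ$t <- summ$df <- summ$p <- summ$power <- NA_real_
  for (i in seq_len(nrow(summ))) {
    tt <- ttest_from_summary(summ$mean1[i], summ$sd1[i], summ$n1[i],
                             summ$mean2[i], summ$sd2[i], summ$n2[i],
                             variant = variant)
    pw <- posthoc_power(summ$mean1[i], summ$sd1[i], summ$n1[i],
                        summ$mean2[i], summ$sd2[i], summ$n2[i], alpha = alpha)
    summ$t[i] <- tt$t; summ$df[i] <- tt$df; summ$p[i] <- tt$p
    summ$power[i] <- pw$power
  }
  class(summ) <- c("group_stats", "data.frame")
  summ
}

#' @export
print.group_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Group comparison: %s (n=%d) vs %s (n=%d)\n",
              x$group1[1], x$n1[1], x$group2[1], x$n2[1]))
  tab <- data.frame(
    parameter = x$parameter,
    g1 = sprintf("%.4f (%.4f)", x$mean1, x$sd1),
    g2 = sprintf("%.4f (%.4f)", x$mean2, x$sd2),
    p = ifelse(x$p < 0.001, "< 0.001", sprintf("%.3f", x$p)),
    power = sprintf("%.4f", x$power))
  names(tab)[2:3] <- c(paste0(x$group1[1], " mean (SD)"),
                       paste0(x$group2[1], " mean (SD)"))
  print(tab, row.names = FALSE)
  invisible(x)
}
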