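#' Pupil-diameter series from landmark annotations
#'
#' Converts per-frame pupillary-margin landmark pairs into a pupil-diameter
#' trajectory: `pd[i]` is the Euclidean distance between the two margin
#' points of frame `i` times the pixel pitch, and `t[i] = i / fps`.
#'
#' @param ann A landmark annotation as returned by [render_video()] or
#'   [read_annotation()].
#' @return A [pupil_trajectory()].
#' @export
pd_from_landmarks <- function(ann) {
  validate_annotation(ann)
  pd <- vapply(seq_along(ann$frames), function(i) {
    fr <- ann$frames[[i]]
    m <- fr$margin
    if (is.null(m) || !is.matrix(m) || !all(dim(m) == c(2L, 2L)))
      stop_invalid("frame %d: annotation must contain exactly two margin points",
                   fr$idx %||% (i - 1L))
    sqrt(sum((m[1, ] - m[2, ])^2)) * ann$pixel_pitch
  }, numeric(1))
  if (any(pd == 0)) warning("coincident margin points give PD = 0 (pd > 0 invariant)")
  pupil_trajectory(pmax(pd, 0), fps = ann$fps, video_id = ann$video_id %||% "annotated")
}

#' Detect the pupil-constriction window
#'
#' Onset is the first frame whose backward-difference constriction velocity
#' `(pd[i-1] - pd[i]) * fps` reaches `v_on` and keeps doing so for `k`
#' consecutive frames; the window ends at the earliest pupil-diameter
#' minimum at or after onset.
#'
#' @param traj A [pupil_trajectory()].
#' @param v_on Onset velocity threshold in mm/s.
#' @param k Number of consecutive supra-threshold frames required.
#' @return A `constriction_window`: list with 1-based `onset_idx`, `end_idx`
#'   (frame 1 is the first recorded frame).
#' @export
detect_constriction_window <- function(traj, v_on = 0.1, k = 2) {
  stopifnot(inherits(traj, "pupil_trajectory"))
  if (!is_scalar_number(v_on) || v_on <= 0) stop_invalid("`v_on` must be positive")
  if (!is_scalar_number(k) || k < 1 || k != round(k))
    stop_invalid("`k` must be a positive integer")
  fps <- attr(traj, "fps")
  pd <- traj$pd
  n <- length(pd)
  v_back <- c(NA_real_, (pd[-n] - pd[-1]) * fps)  # v_back[i] for frame i >= 2
  ok <- !is.na(v_back) & v_back >= v_on
  onset <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run == k) { onset <- i - k + 1L; break }
  }
  if (is.na(onset))
    stop_invalid("no constriction detected (no %d consecutive frames with velocity >= %g mm/s)",
                 as.integer(k), v_on)
  end <- onset - 1L + which.min(pd[onset:n])  # which.min takes the earliest tie
  constriction_window(onset, end, n)
}

#' @rdname detect_constriction_window
#' @param onset_idx,end_idx 1-based frame indices with
#'   `1 <= onset_idx < end_idx <= n_frames`.
#' @param n_frames Number of frames in the trajectory.
#' @export
constriction_window <- function(onset_idx, end_idx, n_frames) {
  onset_idx <- as.integer(onset_idx); end_idx <- as.integer(end_idx)
  if (!(onset_idx >= 1L && onset_idx < end_idx && end_idx <= n_frames))
    stop_invalid("window indices must satisfy 1 <= onset < end <= n_frames")
  structure(list(onset_idx = onset_idx, end_idx = end_idx, n_frames = as.integer(n_frames)),
            class = "constriction_window")
}

#' Transient velocities and accelerations within a window
#'
#' Adjacent-frame finite differences over the constriction window:
#' `v[i] = (pd[i] - pd[i+1]) * fps` (positive while the pupil constricts) for
#' frames `onset .. end-1`, and `acc[j] = (v[j+1] - v[j]) * fps`.
#'
#' @param traj A [pupil_trajectory()].
#' @param window A `constriction_window`.
#' @return List with numeric vectors `velocity` (mm/s) and `acceleration`
#'   (mm/s^2).
#' @export
transient_series <- function(traj, window) {
  stopifnot(inherits(traj, "pupil_trajectory"), inherits(window, "constriction_window"))
  fps <- attr(traj, "fps")
  i0 <- window$onset_idx; i1 <- window$end_idx
  if (i1 - i0 + 1L < 3L)
    stop_invalid("window spans %d frames; at least 3 are needed to compute an acceleration",
                 i1 - i0 + 1L)
  pd <- traj$pd[i0:i1]
  v <- (pd[-length(pd)] - pd[-1]) * fps
  acc <- diff(v) * fps
  list(velocity = v, acceleration = acc)
}

#' Quadratic fit to the pupil-diameter curve
#'
#' Ordinary least squares fit of `y_pd = a x^2 + b x + c` over the window.
#' With `abscissa = "seconds"` (default) `x` is time in seconds so the
#' curvature has units mm/s^2; with `"frames"` `x` is the 0-based frame
#' number, the convention under which reported fitted accelerations are a
#' few 1e-3 in magnitude at typical frame rates.
#'
#' @inheritParams transient_series
#' @param abscissa `"seconds"` or `"frames"`.
#' @return A `quadratic_fit`: list with coefficients `a`, `b`, `c`, residual
#'   sum of squares `rss` and the `abscissa` used.
#' @export
fit_quadratic <- function(traj, window, abscissa = c("seconds", "frames")) {
  stopifnot(inherits(traj, "pupil_trajectory"), inherits(window, "constriction_window"))
  abscissa <- match.arg(abscissa)
  idx <- window$onset_idx:window$end_idx
  if (length(idx) < 3L) stop_invalid("quadratic fit needs at least 3 points")
  x <- if (abscissa == "seconds") traj$t[idx] else traj$frame[idx]
  y <- traj$pd[idx]
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]),
                 rss = sum(stats::resid(fit)^2), abscissa = abscissa),
            class = "quadratic_fit")
}

#' The five dynamic parameters of pupil constriction
#'
#' Runs window detection (unless a window is supplied), adjacent-frame
#' transients and the quadratic fit, and reports the five constriction
#' parameters: mean and maximum constriction velocity (`vpc_mean`,
#' `vpc_max`, mm/s), mean and maximum magnitude of adjacent-frame
#' acceleration (`apc_mean`, `apc_max`, mm/s^2), and the fitted acceleration
#' `apc_fitting = 2|a|` from the quadratic fit. All five are reported as
#' constriction-positive magnitudes; the signed curvature is kept in `fit$a`.
#'
#' @inheritParams detect_constriction_window
#' @inheritParams fit_quadratic
#' @param window Optional precomputed `constriction_window`; `NULL` (default)
#'   detects it.
#' @param fit_span `"window"` fits the quadratic over the constriction window
#'   (default); `"full"` fits it over the whole recording.
#' @return A `kinematic_summary` list: the five parameters, the
#'   `quadratic_fit` and the `constriction_window` used.
#' @examples
#' p <- plr_params(4, 1, latency = 0, duration = 1, recovery_rate = 0,
#'                 noise_sd = 0, profile = "quadratic")
#' tr <- simulate_trajectory(p, fps = 64, record_len = 1.5)
#' kinematic_summary(tr)
#' @export
kinematic_summary <- function(traj, v_on = 0.1, k = 2, window = NULL,
                              abscissa = c("seconds", "frames"),
                              fit_span = c("window", "full")) {
  stopifnot(inherits(traj, "pupil_trajectory"))
  abscissa <- match.arg(abscissa)
  fit_span <- match.arg(fit_span)
  if (is.null(window)) window <- detect_constriction_window(traj, v_on = v_on, k = k)
  ts <- transient_series(traj, window)
  fit_win <- if (fit_span == "full")
    constriction_window(1L, nrow(traj), nrow(traj)) else window
  fit <- fit_quadratic(traj, fit_win, abscissa = abscissa)
  structure(list(
    vpc_mean = mean(ts$velocity),
    vpc_max = max(ts$velocity),
    apc_mean = mean(abs(ts$acceleration)),
    apc_max = max(abs(ts$acceleration)),
    apc_fitting = 2 * abs(fit$a),
    fit = fit, window = window,
    video_id = attr(traj, "video_id")
  ), class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf("Kinematic summary '%s' (frames %d-%d of %d)\n", x$video_id,
              x$window$onset_idx, x$window$end_idx, x$window$n_frames))
  cat(sprintf("  VPC_mean %.4f  VPC_max %.4f  (mm/s)\n", x$vpc_mean, x$vpc_max))
  cat(sprintf("  APC_mean %.4f  APC_max %.4f  APC_fitting %.4g  (mm/s^2, abscissa %s)\n",
              x$apc_mean, x$apc_max, x$apc_fitting, x$fit$abscissa))
  invisible(x)
}

#' Tabulate kinematic summaries
#'
#' @param summaries A list of `kinematic_summary` objects (or of
#'   [pupil_trajectory()]s, which are summarised first).
#' @param ... Passed to [kinematic_summary()] when trajectories are given.
#' @return A data frame with one row per video: the five parameters, the
#'   quadratic coefficients and the (0-based) window indices.
#' @export
kinematics_table <- function(summaries, ...) {
  summaries <- lapply(summaries, function(s) {
    if (inherits(s, "pupil_trajectory")) kinematic_summary(s, ...) else s
  })
  stopifnot(all(vapply(summaries, inherits, logical(1), "kinematic_summary")))
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(video_id = s$video_id,
               vpc_mean = s$vpc_mean, vpc_max = s$vpc_max,
               apc_mean = s$apc_mean, apc_max = s$apc_max,
               apc_fitting = s$apc_fitting,
               a = s$fit$a, b = s$fit$b, c = s$fit$c,
               onset_idx = s$window$onset_idx - 1L,
               end_idx = s$window$end_idx - 1L)
  }))
}
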