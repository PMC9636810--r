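#' Pupillary light reflex parameters
#'
#' Bundle of subject-level parameters describing one pupillary light reflex
#' (PLR): a dark-adapted baseline pupil diameter, a constriction of given
#' amplitude and duration starting `latency` seconds after recording onset,
#' an optional linear redilation afterwards, and additive Gaussian
#' measurement noise emulating manual pupillary-margin marking jitter.
#'
#' @param baseline_pd Dark-adapted pupil diameter in mm.
#' @param amplitude Total constriction in mm (`0 <= amplitude <= baseline_pd`).
#' @param latency Seconds from recording start (light onset) to constriction
#'   onset.
#' @param duration Seconds from constriction onset to the pupil-diameter
#'   minimum; must be positive.
#' @param recovery_rate Post-minimum redilation slope in mm/s (>= 0; 0
#'   disables recovery).
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   in mm.
#' @param profile Shape of the constriction: `"quadratic"` (diameter falls
#'   proportionally to the square of elapsed time), `"logistic"` (sigmoidal
#'   fall, velocity peaking mid-constriction), or `"linear"`.
#' @param steepness Dimensionless slope parameter of the logistic profile
#'   (ignored by the other profiles). Larger values concentrate the velocity
#'   pulse.
#'
#' @return An object of class `plr_params`.
#' @seealso [simulate_trajectory()], [group_preset()]
#' @export
plr_params <- function(baseline_pd = 5, amplitude = 1, latency = 0.5,
                       duration = 1, recovery_rate = 0.3, noise_sd = 0.02,
                       profile = c("quadratic", "logistic", "linear"),
                       steepness = 8) {
  profile <- match.arg(profile)
  for (nm in c("baseline_pd", "amplitude", "latency", "duration",
               "recovery_rate", "noise_sd", "steepness")) {
    if (!is_scalar_number(get(nm))) stop_invalid("`%s` must be a finite scalar", nm)
  }
  if (baseline_pd <= 0) stop_invalid("`baseline_pd` must be positive")
  if (amplitude < 0 || amplitude > baseline_pd)
    stop_invalid("`amplitude` must satisfy 0 <= amplitude <= baseline_pd")
  if (duration <= 0) stop_invalid("`duration` must be positive")
  if (latency < 0) stop_invalid("`latency` must be >= 0")
  if (recovery_rate < 0) stop_invalid("`recovery_rate` must be >= 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (steepness <= 0) stop_invalid("`steepness` must be positive")
  structure(list(baseline_pd = baseline_pd, amplitude = amplitude,
                 latency = latency, duration = duration,
                 recovery_rate = recovery_rate, noise_sd = noise_sd,
                 profile = profile, steepness = steepness),
            class = "plr_params")
}

# Normalised constriction profile s(u) on [0, 1] with s(0) = 0, s(1) = 1.
profile_fraction <- function(u, profile, steepness) {
  u <- pmin(pmax(u, 0), 1)
  switch(profile,
         quadratic = u^2,
         linear    = u,
         logistic  = {
           k <- steepness
           f <- stats::plogis(k * (u - 0.5))
           f0 <- stats::plogis(-k / 2)
           f1 <- stats::plogis(k / 2)
           (f - f0) / (f1 - f0)
         },
         stop_invalid("unknown profile '%s'", profile))
}

# Noise-free pupil diameter at times t (vectorised).
plr_pd <- function(t, p) {
  u <- (t - p$latency) / p$duration
  pd <- p$baseline_pd - p$amplitude * profile_fraction(u, p$profile, p$steepness)
  after <- t > p$latency + p$duration
  if (any(after) && p$recovery_rate > 0) {
    reco <- p$recovery_rate * (t[after] - p$latency - p$duration)
    pd[after] <- pmin(p$baseline_pd, p$baseline_pd - p$amplitude + reco)
  }
  pd
}

#' Simulate a pupil-diameter trajectory
#'
#' Generates a uniformly sampled pupil-diameter (PD) time series for one
#' recording: baseline during the dark lead-in, a constriction of the chosen
#' profile after light onset, optional linear redilation, and i.i.d. Gaussian
#' measurement noise. PD is clipped to stay positive.
#'
#' @param params A [plr_params()] object.
#' @param fps Sampling rate in frames per second (8 for the Casia dialect,
#'   14 for the Zeiss recording dialect).
#' @param record_len Recording length in seconds; must exceed
#'   `latency + duration` so the constriction completes on record.
#' @param seed Optional integer seed; identical seeds give identical series.
#' @param video_id Identifier stored with the trajectory.
#'
#' @return A `pupil_trajectory`: a data frame with columns `frame` (0-based),
#'   `t` (seconds) and `pd` (mm), with attributes `fps` and `video_id`.
#' @examples
#' p <- plr_params(baseline_pd = 4, amplitude = 1, latency = 0, duration = 1,
#'                 recovery_rate = 0, noise_sd = 0, profile = "quadratic")
#' tr <- simulate_trajectory(p, fps = 8, record_len = 1.5)
#' @export
simulate_trajectory <- function(params, fps = 8, record_len = 4, seed = NULL,
                                video_id = "sim") {
  stopifnot(inherits(params, "plr_params"))
  if (!is_scalar_number(fps) || fps <= 0) stop_invalid("`fps` must be positive")
  if (!is_scalar_number(record_len) || record_len <= 0)
    stop_invalid("`record_len` must be positive")
  if (record_len <= params$latency + params$duration)
    stop_invalid("`record_len` (%.3g s) must exceed latency + duration (%.3g s)",
                 record_len, params$latency + params$duration)
  n <- floor(record_len * fps) + 1L
  t <- (seq_len(n) - 1L) / fps
  pd <- plr_pd(t, params)
  if (params$noise_sd > 0) {
    pd <- with_seed(seed, pd + stats::rnorm(n, 0, params$noise_sd))
  }
  pd <- pmax(pd, 1e-6)
  pupil_trajectory(pd, fps = fps, video_id = video_id)
}

#' Construct a pupil trajectory from raw values
#'
#' @param pd Pupil diameters in mm (length >= 3, positive).
#' @param fps Frames per second.
#' @param t Optional time stamps (seconds); defaults to `(0:(n-1))/fps`.
#' @param video_id Identifier.
#' @return A `pupil_trajectory` data frame.
#' @export
pupil_trajectory <- function(pd, fps, t = NULL, video_id = "traj") {
  if (!is.numeric(pd) || length(pd) < 3L)
    stop_invalid("`pd` must be numeric with at least 3 frames")
  if (any(!is.finite(pd))) stop_invalid("`pd` contains non-finite values")
  if (any(pd <= 0)) warning("pupil diameters <= 0 violate the pd > 0 invariant")
  if (!is_scalar_number(fps) || fps <= 0) stop_invalid("`fps` must be positive")
  n <- length(pd)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fps
  if (length(t) != n) stop_invalid("`t` and `pd` lengths differ")
  dt <- diff(t)
  if (any(abs(dt - 1 / fps) > 1e-9))
    stop_invalid("time stamps must be uniform at 1/fps")
  structure(data.frame(frame = seq_len(n) - 1L, t = t, pd = pd),
            fps = fps, video_id = video_id,
            class = c("pupil_trajectory", "data.frame"))
}

#' @export
print.pupil_trajectory <- function(x, ...) {
  cat(sprintf("Pupil trajectory '%s': %d frames at %g fps (%.2f s)\n",
              attr(x, "video_id"), nrow(x), attr(x, "fps"),
              x$t[nrow(x)] - x$t[1]))
  cat(sprintf("  PD range %.3f - %.3f mm\n", min(x$pd), max(x$pd)))
  invisible(x)
}

#' @export
plot.pupil_trajectory <- function(x, ...) {
  plot(x$t, x$pd, type = "l", xlab = "time (s)", ylab = "pupil diameter (mm)",
       main = attr(x, "video_id"), ...)
  invisible(x)
}
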