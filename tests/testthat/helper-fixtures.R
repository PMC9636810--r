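# Shared fixtures, built in code.

noiseless_quadratic <- function(fps = 64, baseline = 4, amplitude = 1,
                                duration = 1) {
  simulate_trajectory(
    plr_params(baseline_pd = baseline, amplitude = amplitude, latency = 0,
               duration = duration, recovery_rate = 0, noise_sd = 0,
               profile = "quadratic"),
    fps = fps, record_len = duration + 2 / fps)
}

full_window <- function(traj) constriction_window(1L, nrow(traj), nrow(traj))

# A tiny annotation with hand-set landmarks (m ACA points per frame).
toy_annotation <- function(margins, acas, fps = 8, pitch = 0.0125) {
  frames <- lapply(seq_along(margins), function(i) {
    list(idx = i - 1L, margin = margins[[i]], aca = acas[[i]])
  })
  structure(list(video_id = "toy", fps = fps, pixel_pitch = pitch,
                 frames = frames),
            class = "landmark_annotation")
}

# O(n^2) pair-counting AUC oracle (ties count one half).
auc_pair_oracle <- function(scores, labels01) {
  pos <- scores[labels01 == 1]; neg <- scores[labels01 == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force 2x2 metrics from explicit counts.
metrics_from_counts <- function(tp, fn, fp, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp); prec <- div(tp, tp + fp)
  list(sensitivity = sens, specificity = spec, precision = prec,
       f1 = if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
            else 2 * prec * sens / (prec + sens),
       balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                           else (sens + spec) / 2,
       accuracy = (tp + tn) / (tp + fn + fp + tn))
}

kappa_from_counts <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Score/label vectors realising a given 2x2 table at threshold 0.5.
vectors_from_counts <- function(tp, fn, fp, tn) {
  list(scores = c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn)),
       labels = c(rep(1L, tp + fn), rep(0L, fp + tn)))
}
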