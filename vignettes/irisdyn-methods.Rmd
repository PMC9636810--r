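---
title: "Methods: pupil-constriction kinematics, frame alignment and classifier evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil-constriction kinematics, frame alignment and classifier evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisdyn)
```

## The problem

In primary angle-closure disease the iris responds more sluggishly to light
than in healthy eyes. Anterior-segment OCT (AS-OCT) video recordings of the
pupillary light reflex (PLR) — dark adaptation, then a torchlight onset —
capture this directly: the pupil diameter (PD), measured as the distance
between the two manually marked pupillary-margin points on each B-scan
frame, falls from its dark-adapted baseline to a minimum over a second or
two. `irisdyn` implements the full desk-scale analysis around that signal:

1. a synthetic generator for PLR trajectories and schematic AS-OCT videos
   with ground-truth landmarks (`simulate_trajectory()`, `render_video()`,
   `make_dataset()`);
2. extraction of five dynamic constriction parameters
   (`kinematic_summary()`);
3. landmark-based rigid alignment of jittered video frames
   (`align_video()`);
4. two-group statistics with post-hoc power (`group_stats_table()`);
5. stratified cross-validated classifier evaluation with eight metrics
   (`cross_validate()`).

## The five dynamic parameters

Within the constriction window, adjacent-frame finite differences give the
transient velocity `v[i] = (pd[i] - pd[i+1]) * fps` (constriction-positive)
and acceleration `acc[j] = (v[j+1] - v[j]) * fps`. The five reported
parameters are

* `VPC_mean`, `VPC_max` — mean and maximum of `v` (mm/s);
* `APC_mean`, `APC_max` — mean and maximum of `|acc|` (mm/s²);
* `APC_fitting` — twice the magnitude of the leading coefficient of the
  ordinary-least-squares quadratic fit `y_pd = a x² + b x + c` over the
  window.

Conventions worth stating explicitly:

* **Magnitudes.** All five parameters are reported constriction-positive.
  Adjacent-frame accelerations change sign along any non-parabolic curve,
  so `APC_mean`/`APC_max` use `|acc|`; for the same reason `APC_fitting`
  is `2|a|` while the signed curvature is preserved in `fit$a`. (A convex,
  decelerating PD curve gives `a > 0`; the package's accelerating quadratic
  test profile gives `a < 0`; both report the same positive magnitude.)
* **Abscissa.** The default fit abscissa is seconds, so `APC_fitting` is a
  genuine mm/s². A `frames` mode divides `a` by `fps²`; published fitted
  accelerations of order 10⁻³ "mm/s²" at 8–14 fps are consistent with a
  frame-index abscissa, so both conventions are available and recorded in
  the output.
* **Window.** The constriction window is detected, not given: onset is the
  first frame whose backward-difference velocity reaches `v_on` (default
  0.1 mm/s) for `k` (default 2) consecutive frames, and the window ends at
  the earliest PD minimum at or after onset. The thresholding necessarily
  cuts the slow head of the constriction, so for analytic profiles the
  extracted `VPC_mean` matches the telescoped closed form over the
  *detected* window, not over the full constriction;
  `kinematic_summary(window = ...)` accepts an explicit window when the
  distinction matters. Ties at the minimum break to the earliest frame; a
  trajectory with no qualifying onset raises a "no constriction detected"
  error rather than returning junk.

The telescoping identity `VPC_mean × window duration = pd[onset] - pd[end]`
holds exactly by construction and is property-tested, as are scale
equivariance (PD in other units scales all five parameters linearly) and
`O(1/fps)` convergence to calculus closed forms on noiseless quadratics.

## The synthetic generator and its calibration

The generator is the package's study-conditions definition: the reference
cohort (159 angle-closure, 210 normal videos; 8 fps Casia and 14 fps Zeiss
recording dialects) is emulated, not downloaded. Each subject draws a
latent constriction velocity `vpc`, an amplitude, a baseline PD and a
latency from truncated normal distributions; duration is derived as
`dur_scale × amplitude / vpc`. PD follows the chosen profile (quadratic,
logistic or linear; logistic is the calibrated default for both groups),
redilates linearly at 0.3 mm/s after the minimum, and carries additive
Gaussian marking noise (default SD 0.02 mm).

Defaults the published protocol does not pin down are package conventions:
a ~0.5 s dark lead-in before constriction onset (mean latency 0.5 s, SD
0.1), baseline PD 4–6.5 mm, 7.5 s recordings.

**Calibration.** At 8 fps with 0.02 mm noise, extraction is not a free
lunch: the onset threshold trims the window, the noisy argmin smears the
window end, and second differences amplify marking noise by
`sqrt(6) × fps² ≈ 157`, putting a noise floor of ≈2.5 mm/s² under
`APC_mean`. The preset constants (`dur_scale`, logistic `steepness`, latent
`vpc` SD per group) were therefore fixed by a one-time calibration
simulation (n = 3000–4000 per group, fixed seeds) so that the
**pipeline-extracted** group means match the reference comparison table:
angle-closure `VPC_mean` 0.4704 mm/s and `APC_mean` 3.5118 mm/s², normal
`VPC_mean` 0.5709 mm/s. They are frozen constants in the source, not
fitted at run time. Two deliberate compromises:

* Window-detection variability floors the extracted `VPC_mean` SD at about
  0.16 mm/s, above the reference SDs (0.1362/0.1296); the latent SDs are
  set so the total spread lands as close as feasible.
* The normal group's `APC_mean` is left at ≈3.95 mm/s² rather than the
  reference 5.26: pushing it up requires a velocity pulse so spiky that the
  extracted `VPC_mean` SD roughly doubles. The group ordering
  (normal faster and more accelerated than angle-closure) is preserved and
  asserted as a calibration-check test.

What the generator does *not* emulate: OCT speckle physics, 3-D
anterior-segment geometry, accommodation or hippus, inter-frame correlated
marking error, or the published maxima (`VPC_max`, `APC_max`), which at
8 fps are dominated by extreme-value noise. Passing tests therefore show
pipeline correctness under the stated noise model, not clinical validity on
real videos.

## Rendering and rigid alignment

`render_video()` draws a schematic B-scan per frame — a bright corneal arc
and an iris band broken by a pupil gap of `round(pd / pixel_pitch)` px —
then perturbs each frame with an independent rigid jitter (rotation about
the image centre, Gaussian SD in degrees; Gaussian pixel shifts) emulating
involuntary eye movement. The annotation records the true post-jitter
landmark coordinates and the injected transforms, giving every downstream
stage an exact oracle.

`estimate_rigid()` is the closed-form 2-D Procrustes/Kabsch solution
(rotation + translation, reflection excluded via the SVD sign correction;
scaling excluded since the physical motion is rigid). Rotation is about the
pixel origin with the translation absorbing the offset. With one landmark
pair the rotation is unidentifiable and a pure translation is returned;
coincident source points with two or more landmarks raise a
degenerate-geometry error naming the frame. `align_video()` maps every
frame onto the first (the reference) and reports pre/post RMS landmark
residuals; because the identity is always a feasible transform, alignment
can never increase the residual. `warp_frame()` resamples by inverse
mapping with bilinear (default) or nearest interpolation, fill value 0
(dark OCT background); rigid transforms preserve distances, so alignment
never changes PD measured from landmarks.

## Group statistics

`ttest_from_summary()` implements the pooled-variance Student t-test in
closed form from group means/SDs/sizes (Welch–Satterthwaite by flag);
`ttest_ind()` wraps `stats::t.test()` on raw samples, and the two are
cross-checked to 1e-12. The default is Student pooled with two-sided
p-values and no multiple-testing correction across the five parameters,
matching the reference analysis conventions. Post-hoc power uses the
noncentral t distribution: `d = |m1 - m2| / pooled SD`,
`ncp = d sqrt(n1 n2 / (n1 + n2))`, `power = P(|T'| > t_crit)` with
`df = n1 + n2 - 2` — the convention of standard power software; for the
large noncentralities in the reference table a normal approximation would
agree to four decimals anyway. The reference table's fitted-acceleration
row is printed to one significant figure; its power (0.9968) is not
recomputable from those inputs and is documented rather than targeted.

## Classifier evaluation

`stratified_kfold()` shuffles within class and deals round-robin, so
per-fold class counts deviate from perfect stratification by at most one.
AUC is the Mann–Whitney pair-counting statistic (midranks; ties one half),
tested against an O(n²) oracle and an independent ROC implementation. The
AUC confidence interval is a stratified bootstrap percentile interval
(default B = 2000, seed recorded); the published work names no interval
method, and bootstrap makes no binormal assumption. Confusion metrics use
a fixed operating threshold (default 0.5 on calibrated scores); undefined
ratios (0/0) are flagged `NA`, never silently 0. Both balanced accuracy
and plain accuracy are emitted, since the reference report lists balanced
accuracy among its criteria but prints a column headed "Accuracy".

The deep temporal network of the reference system (ResNet feature
extractor + 512-unit LSTM) is **out of scope** as a trainable model: its
training data are private and GPU-scale. It is represented by the scoring
interface of `cross_validate()` — any function returning per-video scores,
including `precomputed_classifier()` for exported scores. The shipped
stand-in is a deliberately simple ridge-logistic model on the five
kinematic features, standardised on training folds only and fitted by
full-batch gradient descent (step size from the logistic Lipschitz
constant, zero initialisation, gradient tolerance 1e-8 — deterministic by
construction). Its job is to exercise the harness and the claim that
kinematic features carry class signal (null-calibrated to AUC ≈ 0.5 under
permuted labels), not to reproduce the published AUCs, which are not
reproducible without the private videos.

## Numerical choices and degenerate inputs

* Indices are 1-based in R objects and 0-based in all files; pixel
  coordinates are 0-based, x-right/y-down; angles are degrees in files.
* Quadratic fits use `stats::lm`; exact quadratic input reproduces
  coefficients to 1e-9 with RSS below 1e-12.
* Both-SDs-zero t-tests, single-class group comparisons, single-class AUC,
  sub-3-frame windows and empty frame directories raise explicit errors.
  `run_pipeline()` treats a failed per-video extraction (possible when the
  schematic pixel pitch quantises PD into steps comparable to the
  constriction amplitude) as a quality-control exclusion: the video is
  dropped with a logged count rather than aborting the cohort.
* Every stochastic routine takes a seed and restores the caller's RNG
  state; dataset generation is byte-reproducible from config + seed.

## Problem sizes

The test suite runs the generator end-to-end at 300–500 videos per group
for calibration checks, 159/210 for the recovery experiment (the reference
cohort sizes), 500 simulated datasets (n = 100 + 100, B = 600) for
bootstrap-coverage assessment, 50 000 replicates for the Monte-Carlo power
oracle, and 10 000 replicates for null p-value uniformity. These sizes
give Monte-Carlo standard errors comfortably inside the asserted
tolerances while keeping the whole suite under a few minutes on one core.
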