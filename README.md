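# irisdyn

Dynamic iris analysis for anterior-segment OCT (AS-OCT) videos of the
pupillary light reflex, aimed at angle-closure screening research: the
pupil of an eye with primary angle-closure disease constricts more slowly
and less sharply in response to light than a healthy pupil, and that
kinematic difference is measurable from the pupil-diameter (PD) trace of a
B-scan video. `irisdyn` provides the whole desk-scale pipeline — synthetic
data with ground truth, kinematic parameter extraction, landmark-based
rigid video stabilisation, group statistics with post-hoc power, and
cross-validated classifier evaluation — for methodologists who want every
stage testable without access to clinical recordings.

## What it computes

With PD(t) the per-frame pupil diameter (mm, from the two pupillary-margin
landmarks × pixel pitch) and Δt = 1/fps, the package reports the five
dynamic parameters of pupil constriction over the detected constriction
window:

* transient velocity v_i = (PD_i − PD_{i+1}) / Δt and acceleration
  a_j = (v_{j+1} − v_j) / Δt, summarised as VPC_mean, VPC_max (mm/s) and
  APC_mean, APC_max (mm/s², magnitudes);
* the quadratic fit y_pd = a·x² + b·x + c over the window, with
  APC_fitting = 2|a|.

Around these: per-frame rigid alignment T̂ = argmin Σ‖T(aca_i) − aca_ref‖²
(closed-form 2-D Procrustes, rotation + translation only) for marked
anterior-chamber-angle (ACA) corners; pooled-variance two-sample t-tests
and noncentral-t post-hoc power (d = |m₁−m₂|/s_p, ncp = d·√(n₁n₂/(n₁+n₂)));
and stratified 5-fold cross-validation reporting AUC (Mann–Whitney pair
counting, stratified-bootstrap CI), balanced accuracy, precision, recall,
F1, sensitivity, specificity and Cohen's kappa.

## Worked example

```r
library(irisdyn)

# one synthetic recording: 5.2 mm baseline, 0.9 mm constriction after a
# 0.5 s lead-in, 8 fps, 0.02 mm marking noise
p  <- plr_params(baseline_pd = 5.2, amplitude = 0.9, latency = 0.5,
                 duration = 1.6, recovery_rate = 0.3, noise_sd = 0.02,
                 profile = "logistic", steepness = 12)
tr <- simulate_trajectory(p, fps = 8, record_len = 6, seed = 7, video_id = "demo")
kinematic_summary(tr)
#> Kinematic summary 'demo' (frames 8-17 of 49)
#>   VPC_mean 0.7817  VPC_max 1.7062  (mm/s)
#>   APC_mean 3.5232  APC_max 9.5007  APC_fitting 0.8434  (mm/s^2, abscissa seconds)
```

The window (frames 8–17, i.e. 1.0–2.1 s) brackets the constriction; the
mean constriction velocity 0.78 mm/s is the PD drop divided by the window
duration, and the acceleration magnitudes include the finite-difference
amplification of the 0.02 mm marking noise (see the methods vignette).

Group statistics from published-style summary rows need no raw data:

```r
ttest_from_summary(0.4704, 0.1362, 159, 0.5709, 0.1296, 210)
#> Two-sample t-test (student_pooled): t = -7.2161, df = 367.00, p = 3.09e-12
posthoc_power(0.4704, 0.1362, 159, 0.5709, 0.1296, 210)
#> Post-hoc power: d = 0.7586, ncp = 7.216, df = 367, power = 1.0000 (alpha 0.05, two-sided)
```

End-to-end on a simulated cohort (60 angle-closure vs 80 normal):

```r
kc  <- simulate_group_kinematics("angle_closure", 60, seed = 1)
kn  <- simulate_group_kinematics("normal", 80, seed = 2)
kin <- rbind(kc, kn)
lab <- rep(c("angle_closure", "normal"), c(nrow(kc), nrow(kn)))
group_stats_table(kin, lab)
#>    parameter angle_closure mean (SD) normal mean (SD)       p  power
#>     vpc_mean         0.4742 (0.1570)  0.5558 (0.1744)   0.005 0.8104
#>      vpc_max         1.4055 (0.1924)  1.5444 (0.2059) < 0.001 0.9809
#>      apc_max         7.5105 (2.1699)  8.5745 (1.9436)   0.003 0.8572
#>     apc_mean         3.4288 (1.0676)  4.0953 (1.1061) < 0.001 0.9448
#>  apc_fitting         1.0734 (0.7551)  1.6043 (1.0445)   0.001 0.9119

cross_validate(kin[, 2:6], lab, k = 5, seed = 42, ci_B = 500)
#> Stratified 5-fold cross-validation (seed 42, threshold 0.50)
#> Across-fold means:
#>               auc        auc_ci_low       auc_ci_high balanced_accuracy
#>             0.722             0.532             0.896             0.698
#>         precision            recall                f1       sensitivity
#>             0.716             0.583             0.633             0.583
#>       specificity             kappa
#>             0.812             0.404
```

The angle-closure group is slower on every parameter, and the five
kinematic features alone carry usable class signal (mean AUC 0.72 here).
`run_pipeline()` chains simulate → align → extract → stats → evaluate and
writes all reports; `inst/cli/irisdyn` exposes the same stages as shell
subcommands (`simulate | extract | align | stats | evaluate | run-all`).

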