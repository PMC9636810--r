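Package: irisdyn
Title: Dynamic Iris Kinematics and Angle-Closure Evaluation from AS-OCT Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing dynamic iris behaviour in anterior-segment
    optical coherence tomography (AS-OCT) video recordings of the pupillary
    light reflex. Simulates pupil-diameter trajectories and schematic B-scan
    frame stacks with ground-truth landmarks, extracts the five constriction
    parameters (mean and maximum velocity and acceleration of pupil
    constriction, plus the quadratic-fit acceleration 2a), rigidly aligns
    jittered frames from marked anterior-chamber-angle landmarks, reproduces
    per-group summary statistics with independent-samples t-tests and
    noncentral-t post-hoc power, and evaluates angle-closure classifiers
    with stratified fivefold cross-validation and an eight-metric report
    (AUC with bootstrap confidence interval, balanced accuracy, precision,
    recall, F1, sensitivity, specificity, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
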