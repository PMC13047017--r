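Package: stancekit
Title: Rule-Based Stance Evaluation and Exercise Analysis from Pose Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinematic analysis of 33-point body-landmark sequences from
    markerless pose estimation, aimed at martial-arts stance evaluation and
    exercise tracking from a single lateral camera view. Provides landmark
    sequence input/output with confidence gating, per-frame joint-angle and
    alignment features (knee flexion, trunk and shank inclination, foot
    separation, a posterior weight-shift proxy, toe-visibility line check),
    temporal smoothing of landmark trajectories (moving average, median,
    one-euro), threshold-rule classification of the three fundamental
    Shotokan stances with data-driven threshold calibration, a hysteresis
    state machine for squat and push-up repetition counting with rep-level
    precision/recall evaluation, reaction-time measurement for a punch
    stimulus task, method-agreement statistics (MAE, RMSE, Bland-Altman,
    Pearson with confidence interval, ICC(2,1)), a forward-kinematics
    synthetic skeleton simulator with ground-truth manifests, and a local
    session-summary store with aggregate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
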