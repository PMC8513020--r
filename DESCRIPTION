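Package: gaitfatigue
Title: Four-State Physical Fatigue Diagnosis from Wearable Gait Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing four physical-fatigue states (Low, Moderate,
    High, Very High) during treadmill walking from wearable sensors: a
    synthetic-cohort generator for foot and lumbar (L5-S1) inertial signals,
    surface-EMG envelopes and heart rate with ground-truth heel strikes;
    zero-phase Butterworth preprocessing and heel-strike gait-cycle
    segmentation; 43 per-cycle kinematic and electromyographic features with
    participant-baseline normalization; Borg CR10 fatigue-class labelling and
    heart-rate safety rules; and comparison of six classifiers with confusion
    metrics, feature-importance ranking, feature-reduction and sensor-ablation
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
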