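Package: trunkdx
Title: Sensor-Based Trunk Endurance Assessment and Method-Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for instrumented trunk muscle endurance testing with
    wearable inertial and surface electromyography (EMG) sensors.
    Implements gradient-descent quaternion sensor fusion to estimate the
    trunk (roll) angle from accelerometer, gyroscope and magnetometer
    streams; an endurance-test state machine for the Sorensen (STEET),
    trunk curl (TCSET) and side bridge (SBET) protocols with angle-droop,
    time-cap and manual termination criteria; EMG fatigue indices (RMS,
    average rectified value, maximum rectified amplitude) over epochs;
    normative categorisation and flexor/extensor and side-to-side
    endurance ratios; and inter-method reliability statistics (one-way
    random-effects intraclass correlation with exact F confidence
    intervals, Cronbach's alpha, Bland-Altman limits of agreement).
    A synthetic-data module simulates posture-hold trajectories, inverse
    IMU sensor models, amplitude-modulated EMG and paired method-comparison
    studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
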