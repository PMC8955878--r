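Package: rehabglove
Title: Sensor-Glove Analytics for Assisted Hand Rehabilitation Exercises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recordings from a sensor glove used in
    assisted self-rehabilitation of paretic or plegic hands. Implements
    roll/pitch estimation from a 6-axis IMU via a discrete complementary
    filter, hand-crafted windowed activity criteria based on a smoothed
    difference kernel, a depth-limited decision tree and small temporal
    convolutional networks for classifying sensor windows into six
    exercise types and into correct versus anomalous exercising, a
    gamified star-based session score, a synthetic multi-subject session
    simulator, and the full cross-validation and sensor-ablation
    evaluation protocol (five-fold and leave-one-subject-out) with
    support-weighted metrics and row-normalised confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
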