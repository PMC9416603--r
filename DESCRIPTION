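Package: DualStreamGait
Title: Dual-Stream Convolutional Feature Extraction with ReliefF Selection
    for EMG/IMU Gait Pattern Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising human lower-limb motion patterns (running,
    level walking, stair ascent, ramp ascent) from fused surface-EMG and
    inertial (IMU) recordings.  Implements the full pipeline: a seed-
    reproducible synthetic gait-signal generator, Butterworth conditioning and
    cubic-spline resampling, fixed-length window segmentation with stratified
    splitting, the classical time/frequency feature bank (MAV, VAR, RMS, ZC,
    WAMP, WL, MDF, MNP), a dual-stream convolutional feature extractor trained
    from scratch with backpropagation, multi-class ReliefF feature weighting
    and threshold selection, and classifier benchmarking (SVM, KNN, decision
    tree, random forest) under stratified five-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    e1071,
    class,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    data.table,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
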