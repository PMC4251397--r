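Package: apwkit
Title: Arterial Pressure Waveform Analysis and Multi-Parametric Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-parametric analysis of single-channel arterial
    pressure waveforms sampled at 1 kHz: baseline removal, pulse-by-pulse
    segmentation and anomalous-beat flagging; detection of the three prominent
    points (systolic peak, point of inflection, dicrotic wave) with type-A /
    type-C pulse classification; extraction of hemodynamic features (arrival
    times, ratios R1-R6, the signed augmentation index, RMSSD, RMSE and FWHM
    variance statistics); information-gain feature ranking with MDL entropy
    discretization; training of four classifier families with stratified
    10-fold cross-validation, ROC/AUC reporting and per-subject majority-vote
    predictions. A bundled synthetic waveform generator, calibrated to
    published cohort statistics for hypertensive and healthy groups, provides
    annotated ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    rpart,
    e1071,
    foreign,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
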