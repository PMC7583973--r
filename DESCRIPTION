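Package: afwear
Title: Atrial Fibrillation Detection from Wearable Inter-Beat Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating atrial-fibrillation (AF) detection from
    photoplethysmography-derived inter-beat intervals (IBIs) recorded by a
    wearable device. Provides a synthetic cohort simulator (sinus rhythm with
    respiratory sinus arrhythmia, AF as a gamma renewal process, atrial
    flutter with switching conduction ratios, per-beat quality scores,
    dropout and diurnal activity profiles), five-minute windowing with a
    quality gate and interpretable-time accounting, nRMSSD threshold
    classification calibrated by Youden's J on a recruitment-ordered patient
    split, an unsupervised mutual-information (InfoNCE) sequence encoder with
    one-nearest-neighbour and supervised classification heads, and a
    diagnostic-accuracy reporting suite (sensitivity, specificity, predictive
    values, AUC, activity-stratified results, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
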