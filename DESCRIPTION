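Package: evmced
Title: Blood Biomarker Classifier Development for Multi-Cancer Early Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and evaluation of blood-based biomarker classifiers
    for multi-cancer early detection from extracellular-vesicle (EV) protein
    panels. Implements limit-of-detection aware preprocessing (prevalence
    filtering, LOD imputation, log2 transformation), biomarker selection by
    recursive feature elimination with repeated stratified cross-validation
    maximizing the partial AUC over a high-specificity band, repeated
    stratified train/test resampling of an unpenalized logistic classifier
    with per-subject score averaging, specificity-anchored threshold
    calibration, Wilson score intervals, bias-corrected bootstrap AUC
    intervals, and standardized-coefficient importance. A synthetic cohort
    generator emulating correlated log-normal marker panels with left
    censoring makes the whole pipeline testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
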