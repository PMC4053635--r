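Package: sichml
Title: Machine Learning Prediction of Symptomatic Haemorrhage After Stroke Thrombolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting symptomatic intracranial haemorrhage (SICH)
    after intravenous thrombolysis from unenhanced CT brain images combined
    with clinical stroke severity. Provides a synthetic cohort generator
    (clinical tables, two-section CT phantom volumes, multi-rater radiology
    readings with calibrated inter-rater agreement), a CT preprocessing
    pipeline (rigid registration, section joining, brain masking,
    anomalous-voxel cleaning, global intensity correction), SEDAN and HAT
    prognostic score calculators with univariate logistic odds ratios, a
    soft-margin support-vector classifier with per-sample box constraints
    proportional to NIHSS, and a repeated case-foil evaluation framework
    (distance ranking, modal rank, ten-threshold ROC/AUC, exact binomial
    chance probabilities, bootstrap model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
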