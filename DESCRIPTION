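Package: thermotan
Title: Interpretable Breast Thermography Diagnosis with Tree-Augmented Naive Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretable diagnostic pipeline for infrared breast
    thermography. Reads per-pixel temperature grids exported from thermal
    cameras as spreadsheets, segments the body by temperature thresholding,
    trains a small convolutional network on the thermograms, localizes the
    critical region of interest with a LIME-style perturbation explainer,
    extracts a panel of bilateral thermal asymmetry factors from the
    affected/healthy breast pair, and fits a tree-augmented naive Bayes
    network over the factors and medical-record variables. Includes
    BayesiaLab-style evaluation reports (occurrence/reliability/precision
    confusion tables, mutual-information and G-test node rankings,
    Gini/ROC/lift/calibration indices), stratified K-fold cross-validation,
    and a synthetic cohort generator so the whole pipeline runs without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    png,
    jsonlite,
    readxl
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
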