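Package: edemarec
Title: Locating Recurrence-Prone Sub-Volumes of Glioblastoma Peritumoral
    Edema from ADC Histogram Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting which part of the peritumoral edema around
    a resected glioblastoma is at high risk of harbouring tumor recurrence,
    using first-order histogram features of the apparent diffusion
    coefficient (ADC) map. Implements rigid registration between imaging
    timepoints, construction of the recurrence/non-recurrence edema
    sub-volumes by mask algebra, per-region ADC histogram statistics centred
    on the max/mean ADC ratio, a cohort modelling stage (Spearman and paired
    Wilcoxon tests, L1-penalised logistic screening with cross-validation,
    forward stepwise logistic regression, ROC analysis with Youden
    cutpoints, and SVM/random-forest comparison classifiers), and a
    tile-based heatmap predictor of the recurrence location on a single
    slice. A synthetic phantom generator provides fully seeded test cohorts
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    png,
    e1071,
    randomForest,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
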