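Package: dvhstack
Title: Stacked Ensemble Prediction of Organ-at-Risk Dose-Volume Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-based radiotherapy planning tools for predicting
    achievable organ-at-risk dose-volume histograms (DVHs) from anatomical
    features. DVH curves are compressed to principal-component scores, a bank
    of linear base learners (forward stepwise, ridge, lasso, elastic net) is
    fitted per score, and the learners are combined by stacked generalization:
    leave-one-out metadata predictions are generated for every training case
    and non-negative stacking weights are optimized by active-set non-negative
    least squares. The same metadata drives automatic filtering of training
    cases whose cross-validated weighted-RMSE error is anomalously high.
    Includes a synthetic-cohort simulator with anatomical, dosimetric and
    mislabeling contamination mechanisms, delimited-text readers and writers
    for feature and DVH tables, JSON model serialization, and an experiment
    runner for seeded robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
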