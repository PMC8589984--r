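Package: apacheaudit
Title: Auditing APACHE IVa In-Hospital Mortality Prediction Errors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for auditing when the APACHE IVa severity-of-illness score
    makes in-hospital mortality prediction errors in intensive care cohorts.
    Implements the APACHE Relative Confidence (ARC) statistic, probability
    cutoff calibration against observed mortality, Type I (false positive)
    and Type II (false negative) error labelling, first-24-hour worst-value
    and vital-sign feature engineering, three laboratory missing-data
    strategies (averaged multiple imputation, median fill with missingness
    flags, severity-score decile group means), ADASYN minority oversampling,
    Lasso-penalized logistic feature selection with cross-validated penalty
    rules and an unpenalized refit for inference, and imbalance-aware holdout
    evaluation. A multi-hospital synthetic cohort generator shaped like the
    eICU Collaborative Research Database schema supports end-to-end testing
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
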