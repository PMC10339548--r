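Package: nomostack
Title: Stacked Machine-Learning Nomograms for Ordinal Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds ordinal (three-level) risk-stratification nomograms from
    tabular clinical cohorts.  Provides cohort quality control (truncation,
    min-max normalisation, stratified splitting), lasso-based feature
    selection, a stacked ensemble of five tabular classifiers whose
    out-of-fold probabilistic predictions feed a proportional-odds ordinal
    logistic regression, and a feature-mapping algorithm that projects the
    resulting model-axis nomogram back onto clinical-feature axes.  Includes
    a synthetic-cohort generator that emulates published per-risk-group
    summary statistics, plus an evaluation panel (macro one-vs-rest AUC,
    DeLong tests, bootstrap-optimism calibration curves and decision-curve
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    rpart,
    randomForest,
    xgboost,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
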