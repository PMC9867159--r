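Package: thermoselect
Title: Feature Ranking for Plantar Thermogram Classification by Variational Dropout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts angiosome-level thermal features from plantar
    thermograms (summary statistics, normalized temperature range occupancy,
    estimated temperature, inter-foot temperature differences, hot-spot and
    thermal-change indices), balances two-class feature tables with SMOTE,
    prunes redundant features by correlation with AUCROC tie resolution, and
    ranks features with four selectors: variational-dropout and
    concrete-dropout input gates trained on a small neural network, plus
    L1-logistic and random-forest baselines. Rankings are fused by
    cross-method coincidence and scored with a fixed-configuration RBF
    support vector machine under stratified cross-validation. A synthetic
    thermogram and tabular-benchmark generator makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    e1071,
    pROC,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
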