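Package: rstprep
Title: Rule-Set-Table Guided Data Preprocessing for Clinical Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinician-authored rule set tables (RST) constrain every stage of
    a tabular clinical machine-learning preprocessing pipeline. Rules written
    in a small plain-text syntax (explicit or preferential keep/remove of
    features and samples) are parsed, validated and compiled against a feature
    table, then enforced inside rule-aware implementations of SMOTE
    oversampling, random undersampling, isolation-forest outlier removal,
    correlation-based redundancy filtering, feature scaling and sequential
    forward selection. A fixed manual pipeline and a seeded random search over
    pipeline compositions and hyperparameters (MLDP) are evaluated under
    Monte-Carlo cross-validation with split reuse or dual-center
    train/test protocols, with confusion-matrix metrics, feature-occurrence
    analysis and ANOVA scenario comparisons. A synthetic-cohort generator
    emulates radiomics-style study cohorts with planted informative features,
    redundant feature groups, outliers and center batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
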