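Package: teloRT
Title: Longitudinal Telomere Length and Chromosomal Instability Analysis
    for Radiotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal individual telomere length
    (Telo-FISH/Q-FISH relative fluorescence intensities) and chromosome
    aberration data from radiotherapy patient cohorts. Provides a seeded
    synthetic cohort generator, control-based standardization, outlier
    filtering and imputation of per-telomere measurements, baseline-anchored
    quartile feature engineering of short and long telomeres, repeated
    measures ANOVA with Tukey HSD, hierarchical clustering of longitudinal
    trajectories, linear-regression baselines, and gradient-boosted tree
    models with stratified splitting, cross-validation and
    leave-patients-out evaluation for predicting post-radiotherapy telomeric
    outcomes. A chromosome-aberration arm covers score-sheet parsing,
    clonality correction, per-cell aberration indices and per-cell
    predictive models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
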