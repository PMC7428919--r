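Package: neowarn
Title: Early-Warning Modelling of Late-Onset Neonatal Sepsis from Noninvasive Vital Signs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building and evaluating machine-learning
    early-warning models of late-onset neonatal sepsis (LONS) from routinely
    charted, noninvasive vital signs in neonatal intensive care. Provides a
    synthetic electronic-medical-record generator emulating MIMIC-III-shaped
    NICU event tables with known ground truth; ICD-9 cohort phenotyping and
    sepsis-onset labeling from blood-culture and intravenous broad-spectrum
    antibiotic timing; windowed statistical feature extraction from irregular
    vital-sign series (thirteen statistics over 3/6/12/24 hour windows with
    normality-gated method choices, three-sigma quality filtering, last
    observation carried forward and zero imputation); a wrapper forward
    feature-selection algorithm maximizing AUROC plus average precision with
    six comparator selectors; training-set-only class-imbalance resampling
    (SMOTE, Tomek links, edited nearest neighbours and relatives); and a
    leakage-audited evaluation harness with stratified cross-validation over
    nine classifiers and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    rpart,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
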