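Package: wearadetect
Title: Noninvasive Diabetes Screening from Wearable Night-Time Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting self-reported diabetes mellitus
    from wearable-derived night-time physiology. Provides a synthetic cohort
    generator emulating class-conditional distributions of nightly heart rate,
    heart-rate variability, total sleep time and diurnal distal body
    temperature amplitude; sleep-window phenotyping from 30-s hypnograms;
    diurnal and multiscale-complexity temperature features; rolling
    multi-night window construction with per-week missingness quality
    filters; regularized logistic regression and gradient-boosted tree
    classifiers with subject-disjoint stratified splits; ROC/PRC evaluation
    in balanced and population-imbalanced cohorts; and feature-importance,
    feature-set ablation and chronic-condition specificity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
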