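Package: hepascan
Title: Automated MRI-Based Cirrhosis Diagnosis with a CNN Ensemble and
    Serum-Biomarker Fusion
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a fully automated
    cirrhosis-diagnosis pipeline for liver MRI: mask-guided preprocessing of
    multi-sequence studies (rigid registration, liver-area slice selection,
    percentile clipping, padding, resizing, min-max normalization, online
    augmentation), a five-fold cross-validated ResNet-18 slice-stack
    classifier with Grad-CAM visualization, serum comparator indices (FIB-4,
    APRI), a random-forest fusion of the imaging probability with age and
    eight serum biomarkers (VIF screening, Gini-importance feature selection,
    grid search), and the paired diagnostic-accuracy statistics used to
    compare diagnostic procedures (DeLong, McNemar, Kosinski weighted
    generalized score, calibration, decision-curve analysis). A seeded
    synthetic liver-phantom cohort generator stands in for patient data so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    digest
Config/testthat/edition: 3
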