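Package: sexdiffmri
Title: Confounder-Aware Deep Learning Analysis of Sex Differences in Volumetric Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for identifying sex differences in
    pre-adolescent brain MRI while controlling for study confounders. A compact
    3D convolutional network predicts a binary group label (girl/boy) from
    volumetric images, a general linear model screens the learned predictor
    variables for association with confounders (age, pubertal development,
    socioeconomic status), and confounder-free saliency maps localize the
    discriminative anatomy with atlas-ROI statistics. Downstream analyses
    include effect sizes, prediction-score correlations with cognitive test
    scores, three-condition partial mediation with a permutation null,
    misclassification-by-puberty contingency tests, per-stratum accuracy, ROI
    baseline classifiers, and the DeLong comparison of correlated ROC curves.
    A synthetic-cohort module generates pseudo-brain phantoms with known
    injected effects so every stage is testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
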