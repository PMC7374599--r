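Package: progsig
Title: Cross-Compartment and Temporal Proteomic Signatures of Disease
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering multivariate proteomic signatures
    that separate progressive from stable disease across tissue
    compartments (blood and bronchoalveolar lavage) and over time.
    Provides iterative Hotelling's reduced-T2 sample pruning, volcano-plot
    univariate statistics, l1-penalised (LASSO) signature selection with
    k-fold cross-validation, NIPALS partial least squares discriminant
    analysis with orthogonalisation and VIP scores, paired-classifier
    comparison (Cochran's Q with McNemar post hoc, fold-accuracy ANOVA
    with Tukey HSD), differential Pearson correlation networks with hub
    calling, trajectory PCA of longitudinal signatures, and a synthetic
    cohort generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
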