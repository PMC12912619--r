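Package: amynet
Title: Individual-Specific Amyloid Deposition Networks from Regional PET SUVR
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individual-specific amyloid plaque deposition networks
    from regional PET standardized uptake value ratio (SUVR) tables by an
    add-one-subject perturbation Z-score against a control reference
    correlation network, binarizes them over a sparsity-threshold grid, and
    computes global and nodal graph-theoretic properties (small-world
    metrics, efficiencies, clustering, betweenness centrality) with
    degree-preserving random-graph normalization. Includes normality-gated
    group statistics with Bonferroni-corrected region-wise comparisons,
    staged classification (LASSO feature selection, stratified splitting,
    six classifier families, bootstrap confidence intervals, Monte-Carlo
    Shapley attribution), and a calibrated synthetic cohort generator for
    fully offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    MASS,
    Rcpp,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    nnet,
    class,
    pROC,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
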