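Package: ensdm
Title: Ensemble Species Distribution Modelling with Virtual-Species Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for presence-only ensemble species distribution
    modelling on a geographic grid: occurrence cleaning and 1-km spatial
    thinning, pseudo-absence (background) sampling on the full domain or a
    coastal buffer, a MaxEnt-style penalized logistic model with
    linear/quadratic/product/hinge features and cloglog output, a random-forest
    probability classifier, stratified k-fold cross-validation with AUC and TSS
    at the maximum-Youden threshold, performance-gated AUC-weighted ensembling,
    P10 threshold binarization, geodesic suitable-area accounting, scenario
    projection with net-change reporting, and model interpretation (permutation
    importance, exact Shapley attributions, partial dependence, collinearity
    screening). A synthetic-landscape module generates spatially autocorrelated
    predictor stacks and virtual species with known responses so the whole
    workflow can be validated against ground truth at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pROC,
    optparse
Config/testthat/edition: 3
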