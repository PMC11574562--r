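Package: metabodetect
Title: Serum Metabolome Multi-Cancer Detection Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for building multi-cancer early-detection
    classifiers from untargeted serum LC-MS metabolomics: virtual-lock-mass
    (VLM) per-run mass-error correction and cross-run feature-matrix
    assembly against an annotated metabolite library, curation and
    prevalence/abundance feature filtering, log10 scaling with
    train-referenced single-sample quantile normalization,
    chained-equations (MICE) imputation with gradient-boosted tree
    regressors, and a soft-margin RBF-kernel support vector machine with
    grid search, stratified k-fold cross-validation, subgroup evaluation
    with Wilson confidence intervals, and recursive feature elimination.
    Includes a ground-truthed synthetic multi-batch cohort generator
    (per-run ppm mass drift, batch effects, abundance-dependent
    missingness, stage-structured case mix) so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    tools,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
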