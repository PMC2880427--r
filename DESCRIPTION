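Package: bloodsig
Title: Whole-Blood Gene Expression Classification with PLS and Jackknife
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for building and validating case/control classifiers
    from batched single-channel whole-blood microarray data. Implements
    quality masking (signal-to-noise and flag rules), probe filtering,
    standardization, k-nearest-neighbour imputation, one-way-ANOVA batch
    mean-centering, technical-control handling and replicate averaging;
    a NIPALS PLS1 classifier with leave-one-out cross-validated component
    selection and jackknife testing of regression coefficients; double
    (nested) leave-one-out cross-validation with ROC/AUC, permutation
    null distributions, learning curves and misclassification-covariate
    association tests; a permutation-based global test with per-probe
    influence z-scores and core-probe extraction; gene-set
    over-representation statistics (Fisher and EASE) against GMT gene
    sets; and a seeded synthetic-data generator that reproduces the
    batched study design for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
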