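Package: metayield
Title: Metabolome-Based Grain Yield Prediction with LASSO Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links GC-MS metabolite intensity profiles of crop source organs
    (flag leaf, glume, lemma) to grain yield. Implements the full inference
    chain used in metabolome-to-yield studies: missingness filtering, K-nearest
    neighbour imputation, optional log2 transform, L1-penalised least squares
    (coordinate descent with cross-validated penalty selection), repeated
    75/25 train-validation resampling with a per-metabolite detection-rate
    stability statistic, and a detection-rate-thresholded multiple-regression
    refit with per-metabolite variance partitioning. A synthetic-data module
    emulates a factorial field design (organ x stage x condition x genotype x
    trial) with block-correlated log-scale intensities, sparse linear yield
    effects and controlled missingness, so every stage can be validated
    against known ground truth. Small agronomic utilities (delta 13C notation,
    grain nitrogen yield, harvest index, thousand-kernel weight, normalized
    difference spectral indices, per-metabolite factorial ANOVA) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
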