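Package: deepsol
Title: Deep Residual Networks for Aqueous Solubility Prediction from
    Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curation of experimental aqueous-solubility datasets
    (unit normalisation to logS in mol/L, canonical-SMILES consistency,
    InChIKey deduplication) and regression of logS from 881-bit PubChem
    substructure fingerprints with deep one-dimensional residual
    convolutional networks and shallow fully-connected baselines.
    Includes negative-R-squared least-squares training, 90/10 split and
    k-fold cross-validation protocols, evaluation metrics (R-squared,
    RMSE, percent-within-10-fold, solubility-category accuracy,
    bootstrap confidence intervals), and a seeded synthetic-data
    generator with a planted additive substructure-contribution
    mechanism for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineOB,
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
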