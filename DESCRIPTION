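Package: ilgen
Title: Generative Design and Melting-Point Screening of Ionic Liquids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end workflow for computational design of low-melting
    ionic liquids. Curates ion and melting-point datasets, trains soft-label
    logistic "ion scorers" that quantify how IL-like a cation or anion is,
    fits a conditional variational autoencoder over SMILES strings for
    score-conditioned ion generation, removes chemically implausible
    structures with synthetic-accessibility and substructure filters, and
    ranks exhaustively combined cation-anion pairs by predicted melting
    point. All stages run on bundled synthetic corpora so the pipeline is
    testable offline and fully seed-reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    pROC,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
SystemRequirements: OpenBabel (the 'obabel' executable on PATH)
Config/testthat/edition: 3
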