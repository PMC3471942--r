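Package: ddgforest
Title: Random Forest Prediction of Mutation-Induced Protein Stability Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in protein folding free energy (ddG) caused by
    single- and multiple-point mutations with a Random Forest regression model
    trained on 41 sequence- and structure-derived features: evolutionary
    information from position-specific scoring matrices, secondary structure and
    solvent accessibility of the mutated sites, relative composition and
    physicochemical differences between wild-type and mutant sequences,
    tetra-peptide fragment potentials learned from contrasting reference corpora,
    and four-body fragment potentials defined on a Delaunay tessellation of the
    C-alpha trace. Every mutation is paired with its hypothetical reverse
    mutation (whose ddG is the exact negation, free energy being a state
    function), which balances the training set and provides a robustness test.
    Cross-validation folds respect 30% sequence-identity clustering so homologous
    proteins never straddle the train/test split. A synthetic-data generator
    emulates every input format so the full pipeline runs and is tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    randomForest,
    Biostrings,
    bio3d,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
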