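Package: convboost
Title: Cell-Penetrating Peptide Classification with a Convolutional and
    Gradient-Boosting Soft-Voting Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether short peptides (5-30 residues) are
    cell-penetrating from sequence- and structure-based molecular
    descriptors. Computes physicochemical descriptors from a
    residue-template molecular graph (molecular weight, topological polar
    surface area, Crippen logP, hydrogen-bond donors and acceptors,
    rotatable bonds, sp3 carbon fraction, nitrogen and oxygen counts,
    charged-group counts), Eisenberg-scale hydrophobicity and hydrophobic
    moments, amino-acid, pseudo amino-acid and dipeptide compositions.
    Assembles named feature compositions with Kendall-correlation
    redundancy filtering, and classifies with a soft-voting ensemble of a
    one-dimensional convolutional neural network and a Bayes-tuned XGBoost
    model, evaluated by stratified ten-fold cross-validation. Includes a
    synthetic generator of cationic, amphipathic, Arg/Lys-rich peptide
    datasets for end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
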