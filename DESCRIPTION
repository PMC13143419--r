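Package: pepfp
Title: Count-Based Molecular Fingerprints for Peptide Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hydrogen-suppressed atom-level molecular graphs from
    amino-acid sequences using embedded residue templates, computes hashed
    molecular fingerprints (circular/ECFP-style, topological-torsion paths,
    and all-connected-subgraph) in count and binary variants with modulo
    folding, and couples them to class-weighted gradient-boosted-tree models
    for peptide property prediction. Includes control experiments (sequence
    shuffling, count-versus-binary ablation, charged-motif stress test), a
    synthetic peptide-dataset generator with planted composition, motif, and
    size-regression labels, brute-force enumeration oracles for testing, and
    imbalanced-classification metrics (AUROC, average precision, MCC, F1,
    MAE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    xgboost,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    methods,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC,
    withr
Config/testthat/edition: 3
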