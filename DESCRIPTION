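Package: dnahotspot
Title: Prediction of Hot Spot Residues at Protein-DNA Interfaces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of hot spot residues at protein-DNA
    binding interfaces. Parses PDB-format complexes, computes per-residue
    solvent-accessible surface area (Shrake-Rupley) in bound and unbound
    states, derives a 24-feature structural encoding including interfacial
    neighborhood properties, performs two-step feature selection (SVM-based
    recursive feature elimination followed by Pearson-correlation redundancy
    pruning), trains an RBF-kernel support vector machine with grid-searched
    hyperparameters, and evaluates predictions with standard binary
    classification metrics (sensitivity, specificity, precision, F1, accuracy,
    Matthews correlation coefficient, ROC/AUC). Ships a synthetic-fixture
    generator (toy protein-DNA complexes and labelled feature tables) so the
    full pipeline is testable without external data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
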