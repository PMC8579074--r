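Package: shellscore
Title: Protein-Ligand Binding Affinity Scoring from Residue-Atom Contact Shells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Structure-based scoring of protein-ligand binding affinity (pKd)
    from rotation-free contact features. Each ligand atom is surrounded by
    concentric distance shells and, per shell, the number of contacts between
    the 21 protein residue classes and the 8 ligand atom classes is counted,
    yielding a 168 x N feature image. A small 2D convolutional neural network
    regressor (implemented in R on BLAS matrix products) maps the image to
    pKd, trained with a composite Pearson/RMSE loss, early stopping and
    seed-ensembling. Also provides scoring-power metrics, PDBbind-style index
    parsing and leakage-free train/validation/test splitting, symmetry-aware
    (optimal-assignment) ligand RMSD with decoy binning, feature-ablation
    importance, and a fully seeded synthetic-complex generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    withr,
    optparse,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
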