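Package: decoyrank
Title: Learning-to-Rank Quality Assessment of Protein Decoy Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Global model quality assessment for protein structure
    prediction. Decoy models of a target are first ordered by a pairwise
    learning-to-rank model (ranking-as-classification over feature
    differences) trained on structural features: distance-dependent and
    backbone-torsion knowledge-based potentials, secondary-structure and
    solvent-accessibility agreement features, and optional external
    per-model score tables. The top five ranked models then serve as
    references in a quasi-clustering stage that scores every model by its
    mean GDT_TS (or TM-score) to the references. Includes CASP-style
    evaluation metrics (Diff, MCC, AUC, Loss, per-target and pooled
    Pearson correlation, top-k overlap), synthetic decoy and
    planted-weight generators for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
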