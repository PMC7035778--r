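Package: sampn
Title: Self-Attention Message Passing Networks for Molecular Property
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Directed-edge message passing neural networks with a
    dot-product self-attention readout for quantitative
    structure-property relationship (QSPR) regression on molecular
    graphs, e.g. lipophilicity (logP) and aqueous solubility (logS).
    Converts SMILES into directed chemical graphs with one-hot
    atom/bond features, trains single- or multi-target models with a
    masked loss and an Adam optimizer with warm-up/decay schedule,
    supports stratified k-fold cross-validation, grid search over the
    hyperparameter lattice, an ECFP/random-forest baseline, and
    per-atom attention coefficients rendered as diverging-colour
    molecule heatmaps. Includes a deterministic synthetic-molecule
    fixture generator so the whole pipeline is testable without
    external datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    ChemmineOB,
    randomForest
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
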