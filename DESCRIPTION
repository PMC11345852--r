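Package: perturbpheno
Title: Interface-Guided Coding-Variant Phenotyping for Perturb-Seq Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for variant-barcoded overexpression
    (Perturb-seq/SEUSS style) screens that phenotype coding variants of a
    transcription factor by their single-cell transcriptomes. Provides a
    negative-binomial screen simulator with planted phenotype classes,
    single-cell QC/normalisation/HVG/cell-cycle-regression/PCA/graph
    clustering, Hotelling two-sample T-squared scoring of each variant
    against wild-type and loss-of-function controls with WT-like /
    LoF-like / hypomorphic calls, pooled-screen barcode fitness,
    protein-DNA interface residue calling from PDB structures with
    Shrake-Rupley burial classes, single-base-substitution missense
    library design, conditional-MLE odds ratios with exact tests, and a
    random-forest variant effect classifier stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    irlba,
    RANN,
    randomForest,
    bio3d,
    Biostrings,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
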