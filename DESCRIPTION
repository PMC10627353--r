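Package: forkDR
Title: Forked Multi-Branch Neural Regression for Drug Response
    Prediction from Multi-Omics and Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts ln(IC50) drug sensitivity for drug-cell-line pairs with a
    forked (multi-branch) neural regressor in which drug structural descriptors,
    bulk multi-omics blocks and sampled single-cell expression profiles are each
    processed by a dedicated subnetwork before a linear fusion head. Provides
    SMILES featurization backends, a Seurat-convention single-cell preprocessing
    pipeline (QC, log-normalization, variable-gene selection, cell-cycle module
    scoring, scaling), leakage-safe leave-cell-out / leave-drug-out dataset
    assembly with median-padded single-cell sampling, Hyperband hyperparameter
    search, a six-metric regression evaluation suite with concatenated-input
    baselines, and a synthetic cohort generator with planted bilinear signal for
    download-free testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
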