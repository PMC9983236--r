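Package: TMEcrosstalk
Title: Tumor Microenvironment Cell-Type Co-Occurrence and Ligand-Receptor
    Crosstalk Analysis from Paired Bulk and Single-Cell Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of tumor-stroma crosstalk from paired
    single-cell and bulk RNA-seq data. Infers a cell-type co-occurrence
    network by correlating bulk expression with signature-based cell-type
    abundance estimates, scores ligand-receptor interactions between
    annotated clusters with a label-permutation null, computes binned-control
    module scores and single-sample gene-set enrichment (ssGSEA), and
    stratifies bulk cohorts for Kaplan-Meier survival analysis. Ships a
    negative-binomial simulator that generates paired single-cell and bulk
    datasets with planted, recoverable ground truth (correlated cell-type
    proportions, cluster-specific ligand-receptor pairs, gene-signature
    hazard effects) so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, Network, Survival,
    CellBiology
RoxygenNote: 7.3.3
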