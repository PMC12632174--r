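Package: circuitscan
Title: Inference of Initiating Cell Circuits of Pulmonary Inflammation
    from Single-Cell UMI Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for inferring treatment-specific initiating
    cell circuits from single-cell RNA-seq UMI count matrices of perturbed
    lungs. Covers quality control and log-normalization, per-sample
    consensus highly-variable-gene selection, PCA/kNN/Leiden clustering
    with two-tier marker-based cell-type annotation, per-cell-type
    Welch-test differential expression with BH correction, gene-signature
    scoring, GSVA-style single-sample enrichment, preranked GSEA, induced
    ligand-receptor connectome construction, and NicheNet-style ligand
    activity scoring. Ships a negative-binomial perturbation simulator
    that plants known cell types, cytokine programs and sender-receiver
    circuits so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, DifferentialExpression,
    GeneSetEnrichment, Network, CellBiology, Software
RoxygenNote: 7.3.3
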