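Package: tecdyn
Title: Trajectory and Tissue-Specific-Antigen Kinetics for Medullary Thymic
    Epithelial Cell scRNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative procedures for studying medullary thymic epithelial
    cell (mTEC) development from droplet single-cell RNA-seq: pair-based
    cell-cycle phase scoring, curation of tissue-specific-antigen (TSA) gene
    sets from tissue detection tables, per-cell and per-sample gene-set
    detection statistics with UMI down-sampling normalisation, cell-subsampling
    null distributions with z-score tests, hypergeometric gene-set overlap
    enrichment, reference-based cluster label transfer, reporter/marker
    quadrant analysis, and start-anchored branching pseudotime with smoothed
    expression profiles. A synthetic branching-trajectory generator with full
    ground truth (TAC-TEC branch point, lagged lineage reporter, stochastic TSA
    mosaic, Aire/Fezf2 program timing, ablation/recovery time course) makes
    every stage testable without external data.
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
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    mclust
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Software
RoxygenNote: 7.3.3
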