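Package: chromembed
Title: Genomic Region Embeddings for Single-Cell ATAC-seq Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of genomic regulatory regions
    from single-cell ATAC-seq binary accessibility matrices using a
    skip-gram model with negative sampling, where each cell is treated as a
    document and its accessible regions as words whose context is simulated
    by shuffling. Region embeddings are pooled by averaging into cell
    embeddings for clustering, visualization and reference-based cell-type
    annotation. Pre-trained region models can be transferred to unseen
    datasets by mapping query regions onto the reference consensus region
    set via genomic-interval overlaps, without retraining. Includes
    clustering evaluation metrics (ARI, AMI, homogeneity, Gini, RAGI), a
    dropout-corruption simulator for robustness studies, a synthetic
    accessibility-matrix generator with planted cell types, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
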