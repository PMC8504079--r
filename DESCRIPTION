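Package: aiomics
Title: Artificial Image Objects for CNN Classification of Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transforms gene-level expression matrices into artificial image
    objects (AIOs): each gene is assigned a fixed pixel coordinate by genomic
    position and its rescaled expression (0-255) becomes the pixel intensity,
    so that convolutional neural networks can classify samples without any
    feature selection. Provides the full protocol around the encoding:
    expression preprocessing (log2, per-gene min-max rescaling, shared-gene
    ordering), deterministic and invertible gene-to-pixel maps for grayscale
    and multi-channel layouts, native two-branch 2D and 1D convolutional
    classifiers, stratified k-fold cross-validation with weighted multiclass
    metrics, a per-gene expression-correlation diagnostic for dataset shift,
    Kaplan-Meier and log-rank comparison of classifier calls against
    reference calls, and a synthetic cohort generator with block-correlated
    genes, planted label effects, dataset shift and label-linked survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
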