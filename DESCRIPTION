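Package: spacomm
Title: Cell-Type Communication Networks from Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers how neighboring cell types regulate the expression of
    highly variable genes from single-cell spatial transcriptomics data.
    For each cell type, expression of its highly variable genes is
    regressed on z-scored neighbor-cell-type scores with a multi-response
    partial least squares (NIPALS PLS2) model; coefficients are filtered by
    a two-stage correlation t-test with Benjamini-Hochberg false discovery
    rate control, clustered per cell type by k-means with silhouette-based
    model selection, and aggregated into a directed multiple-input
    multiple-output cell-type communication graph with path attenuation.
    Genes are labeled as communication-related from annotation text via
    keyword lists and classified with a multilayer perceptron. Includes a
    seeded synthetic-data generator with planted neighbor-type effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    nnet,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
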