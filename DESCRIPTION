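Package: dbitscreen
Title: Spatial CRISPR Screen Readout for Deterministic Barcoding in Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Readout pipeline for spatially barcoded in-tissue CRISPR screens:
    flank-anchored extraction of spatial barcodes, UMIs and sgRNA spacers from
    paired-end reads, mismatch-tolerant whitelist matching, UMI deduplication
    into a pixel-by-sgRNA count matrix, pixel-level perturbation labeling,
    nearest-control perturbation signatures with score-based filtering,
    shared-nearest-neighbor clustering with silhouette-guided resolution
    selection, Wilcoxon differential expression, and ROC benchmarking of
    pooled versus spatial guide detection. Includes a chemistry-faithful
    simulator of clonal tissues, sgRNA reads and negative-binomial expression
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    cluster,
    igraph,
    methods,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
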