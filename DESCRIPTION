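Package: scopelink
Title: Linking Live-Cell Imaging to Single-Cell RNA-Seq via Optically
    Barcoded Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for microwell single-cell RNA-Seq
    experiments that use dual-barcoded mRNA capture beads, in which each
    bead carries both a cell-identifying sequencing barcode and an
    optical barcode (a combination of ligated oligonucleotides decodable
    by cycles of reversible fluorescence hybridization). Includes a
    synthetic-data generator for every pipeline input (pool-indexed
    bead-free libraries, hybridization image stacks, live-cell images,
    barcoded expression reads), construction of the sequencing-to-optical
    barcode look-up table, optical demultiplexing of hybridization image
    stacks, cell segmentation and imaging-feature extraction, linking of
    imaging records to expression profiles across array pieces, species
    mixing (barnyard) validation statistics with multiplet detection, and
    correlation of imaging phenotype with gene expression via PCA and
    permutation-based gene set enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    EBImage,
    jsonlite,
    Matrix,
    methods,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
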