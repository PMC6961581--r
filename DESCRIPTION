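Package: bagseq
Title: Single-Cell DNA and RNA Profiling from Split-Pool Barcoded Gel-Bead Libraries
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for processing single-cell sequencing libraries in which each
    cell's nucleic acids are captured in a gel bead and barcoded by split-and-pool
    synthesis. Covers read-structure validation and extraction of composite cell
    barcodes and varietal tags (UMIs), barcode-rank cell calling, collapse of reads
    into uniquely tagged templates, empirical genome binning with GC-corrected
    normalization, circular binary segmentation and grid-search ploidy estimation
    for single-cell copy-number profiles, consensus (error-corrected) base calling
    with trinucleotide-context error matrices, SNV-based cell-source identity and
    cross-contamination estimation including barcode-collision expectations, gene
    expression quantification with PCA marker analysis, and a synthetic-data
    generator that emulates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
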