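Package: lggcna
Title: Shallow Whole-Genome Copy-Number Aberration Calling and Survival
    Scanning for Diffuse Low-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Depth-of-coverage copy-number analysis for shallow whole-genome
    sequencing of diffuse low-grade glioma, exercised end-to-end on synthetic
    cohorts with known ground truth. Implements fixed-width genomic binning
    with GC/mappability loess correction and blacklist filtering, recursive
    binary segmentation of log2 ratios, tumor-cell-fraction-calibrated
    gain/loss calling with subclonal cell-fraction estimation anchored on a
    clonal event, a genome-wide permutation log-rank survival scan with
    fusion of consecutive significant regions and two-stage multiple-testing
    correction, segment-to-region calling for external segmented cohorts,
    and classification of spatial and temporal intratumoral heterogeneity of
    copy-number aberrations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
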