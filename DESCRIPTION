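Package: broadscan
Title: Sequence Determinants of Broad Enhancer Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline relating short DNA sequence patterns to the
    breadth of enhancer activity across cellular contexts. Provides position
    weight matrix scanning with exact P-value threshold calibration against
    non-uniform genomic backgrounds, dinucleotide repeat motif (DRM)
    enrichment statistics with replicate negative sets, linear support vector
    machine classification of enhancer classes from DRM, 6-mer spectrum, or
    transcription factor motif features with cross-validated ROC/PR curves,
    matched genomic background sampling, and analysis of transcription factor
    motif GC/CpG composition versus tissue specificity of expression. A
    synthetic-data module generates genomes, enhancer catalogs, motif sets,
    and TF expression tables with known planted structure so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
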