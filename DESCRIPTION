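Package: ampliconHDR
Title: Classify HDR and NHEJ Editing Outcomes in CRISPR Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies gene-editing outcomes from single-orientation amplicon
    deep-sequencing reads. Reads are quality-filtered, collapsed to unique
    sequences, frequency-filtered, and anchored to the amplicon primers; each
    surviving target sequence is globally aligned to the wild-type amplicon
    with an affine-gap Needleman-Wunsch aligner and classified as precise
    homology-directed repair (HDR, matching an ssODN donor template),
    imprecise end-joining (NHEJ, a non-programmed indel near the Cas9 cut
    site), wild type, or ambiguous. Per-sample summaries report HDR and indel
    percentages, the HDR:indel ratio, and fold enrichment between conditions.
    A configurable simulator generates amplicon read sets with known allele
    mixtures and sequencing error for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    methods,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
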