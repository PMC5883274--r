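Package: nucmark
Title: Constitutive Marker Discovery for Brain Nuclei from Paired-Region Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying constitutive molecular markers
    of discrete brain nuclei from paired nucleus-versus-surround microarray
    contrasts, as used in songbird song-system transcriptomics. Covers
    sequence- and alignment-level probe curation (cloning-artifact detection,
    multi-locus and unaligned probe removal, strand-aware gene annotation),
    two-channel background correction and print-tip loess normalization with
    common-reference orientation, low-signal and high-variance probe filters,
    empirical-Bayes moderated t-statistics with Benjamini-Hochberg or Storey
    adjustment, calibration of significance cutoffs against an independent
    in-situ-validated gene label set, majority-rule probe-to-gene scoring with
    redundant-probe collapsing, cross-contrast marker intersection, and
    hypergeometric gene-set over-representation analysis. Includes a
    synthetic-data generator that emulates the paired laser-capture designs
    the pipeline expects, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
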