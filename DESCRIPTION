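Package: fusionscape
Title: Gene Fusion Discovery and Characterization from Bulk RNA-Seq with
    Copy-Number Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing gene fusions in bulk
    tumour RNA-seq cohorts. Implements outlier-expression-driven breakpoint
    detection for single-end SOLiD color-space reads (exon-level RPKM,
    modified cancer outlier profile analysis, exon walking), consensus
    assembly of partially mapped junction reads with a dibase color-space
    codec, an internal seed-and-extend split aligner for junction placement,
    a six-rule curation filter for external fusion-caller outputs,
    copy-number-based classification of fusion formation mechanisms from
    segmented SNP-array profiles, chimeric-transcript structure and reading
    frame prediction, cohort-level recurrence and hotspot reporting, and a
    deterministic synthetic-cohort simulator used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
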