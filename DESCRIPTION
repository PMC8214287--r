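Package: lrsv
Title: Informative-Read Classification and Call-Set Merging for Long-Read Structural Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Utilities for the bespoke stages of a two-aligner, two-caller
    structural-variant pipeline for PacBio-style long reads: per-read feature
    extraction from SAM alignments (CIGAR/MD edit statistics, soft-clip
    lengths, binned edit density), a small fully-connected neural network that
    flags "informative" reads worth re-aligning with a slower, SV-aware
    aligner, harmonization and merging of two aligners' SAM outputs, and
    redundancy-aware merging of two SV callers' VCF call sets with
    unique-supporting-read filtering. A synthetic-data module generates toy
    references with injected structural variants, error-prone long reads,
    labelled alignment records, and paired caller VCFs so every stage is
    testable without external aligners or callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    Biostrings,
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
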