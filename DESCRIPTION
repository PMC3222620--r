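Package: tehits
Title: Batch Processing and Extraction of Transposable-Element Hits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes repeat-search reports against a genome assembly.
    Parses BLAST tabular, RepeatMasker .out, and e-PCR tabular hit files into
    a tidy hit table with orientation-normalized 1-based coordinates, merges
    overlapping or nearby hits into single loci, applies quality filters
    (length, mismatches, gaps, bit score, E-value, best-N per query), splits
    hits by query or repeat family, and extracts the hit sequences - with an
    optional flanking buffer clamped to sequence ends - from an indexed FASTA
    database into per-group FASTA files and dialect-faithful hit tables.
    Includes a command-line entry point, FASTA cleanup and hit-file splitting
    utilities, and a seeded synthetic-genome fixture generator with planted,
    divergence-mutated repeat copies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    withr,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
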