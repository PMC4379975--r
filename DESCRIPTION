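Package: imssr
Title: Detection and Analysis of Imperfect Microsatellites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Genome-wide identification and analysis of imperfect
    microsatellites (simple sequence repeats with motif mismatches).
    Implements a seed-and-extend detector for mono- to hexanucleotide
    repeats under a fixed-penalty mismatch scoring model, genome-level
    mismatch abundance statistics with an observed-versus-expected
    mismatch partition, permutation-based multivariate tests (PERMANOVA
    and canonical analysis of principal coordinates), classification of
    SNPs inside repeat tracts into M0/M1 allele-match types with Yates'
    chi-square association tests, inbred-line panel utilities for
    polymorphic repeat loci, and a seeded synthetic-genome generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
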