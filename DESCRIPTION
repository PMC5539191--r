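Package: plastid
Title: Reference-Free Chloroplast Genome Assembly from Whole-Genome Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies chloroplast-derived reads inside whole-genome shotgun
    sequencing data using the characteristic structure of the k-mer frequency
    spectrum (a single-copy peak accompanied by an inverted-repeat peak at
    twice its frequency) and assembles a finished circular plastome through
    five staged rounds of read selection, De Bruijn assembly across a sweep
    of K values and read-batch sizes, homology and size filtering, assembly
    ranking, inverted-repeat-aware overlap merging and circularization,
    spanning-read re-scaffolding, and iterative gap filling driven by
    positive/negative k-mer selection. Includes a paired-end read simulator
    with LSC-IR-SSC-IR plastome architecture and a nuclear background for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    withr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
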