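Package: stescan
Title: Sliding-Window Detection and Randomization Testing of Sperm
    Transmission Elements in Bivalve Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Locates short sperm transmission element (STE) motifs in the
    large unassigned regions (LURs) of bivalve mitochondrial genomes.
    Implements a calibrated fixed-width sliding-window scan with an exact
    match/mismatch scoring scheme, LUR extraction from annotated circular
    genomes under protein-coding/rRNA boundary rules, a Monte-Carlo
    randomization test against composition-matched random sequence with an
    exact Poisson-binomial analytic oracle, similarity and upstream-flank
    reporting for candidate motifs, a neighbor-joining overview phylogeny
    with bootstrap support, and a synthetic annotated-genome generator
    with planted motif copies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
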