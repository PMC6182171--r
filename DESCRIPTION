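Package: erosionscan
Title: Screening for Independently Eroded Conserved Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts deeply conserved transcription factor binding sites
    from a reference-anchored multiple genome alignment using
    information-weighted position weight matrix (MATCH) scoring, a
    conservation-bin-matched shuffled-motif empirical null and phylogenetic
    branch-length (BBL) conservation scores; detects binding sites eroded
    in two or three independent target lineages relative to declared
    outgroup species; and tests the top-ranked erosion set for shared
    biological function with GREAT-style basal-plus-extension region and
    gene enrichment tests and non-overlapping permutation overlap tests.
    Includes a deterministic synthetic-world generator with planted
    conserved and eroded sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
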