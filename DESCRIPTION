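Package: cladesig
Title: Discovery of Conserved Signature Indels and Proteins from Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for discovering clade-specific
    molecular markers from sets of predicted proteomes. Implements greedy
    identity clustering of protein families, selection of core families,
    progressive multiple alignment with conserved-block trimming,
    concatenated-supermatrix construction, distance-based phylogeny with
    midpoint rooting and bootstrap supports, detection of conserved signature
    indels (CSIs) with flanking-conservation and group-specificity rules and
    insertion/deletion polarity calling, and detection of conserved signature
    proteins (CSPs) from homology-search hit tables. Includes a sequence
    simulator that plants indel and gene-gain events on a known tree so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
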