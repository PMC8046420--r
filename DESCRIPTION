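Package: condensinTASEP
Title: Stochastic Lattice Models of Condensin Translocation Through
    Transcribed Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gillespie simulation of condensin (SMC complex) translocation
    along a one-dimensional chromatin lattice carrying a transcribed gene.
    Implements three kinetic models: a totally asymmetric simple exclusion
    process (TASEP) for RNA polymerase with condensin pushing and bypass; a
    TASEP-with-pauses ("backtrack") model in which polymerases switch between
    mobile and backtracked states and backtracked polymerases are hard
    obstacles; and an immobile-obstacle model used as a direction-symmetry
    baseline.  A two-stage protocol (RNAP-only burn-in, then single-condensin
    traversal) yields stationary RNAP occupancy profiles and ensemble
    condensin residence-time profiles, together with shape statistics
    (termination-zone enrichment, 5' tilt, exponentiality), a synthetic
    ChIP-like track generator for testing model/data comparisons, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
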