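Package: rfbs
Title: Realized and Fundamental Biome Shifts on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the evolution of established (realized) and enabled
    (fundamental) biome affinities along time-calibrated phylogenies. Species
    hold, for each biome, a non-affinity, an enabled affinity, or an
    established affinity; affinities change anagenetically through single and
    lock-step gains and losses, and are inherited asymmetrically at
    cladogenesis through equal-, subset-, and split-inheritance scenarios.
    Provides Bayesian Metropolis-Hastings inference with multiplier proposals,
    joint ancestral-state sampling at nodes and branch-start corners,
    tip-ambiguity coding with include/exclude/adjacency constraints, forward
    simulation of trees and character histories, and a binary presence/absence
    (dispersal-extinction-cladogenesis style) baseline model for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
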