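Package: anchorphylo
Title: Phylogenetic Analysis of Numeral Anchor Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the evolution of numeral anchor systems (restricted,
    anchor-2, anchor-5, anchor-10 and related types) as a discrete character
    on rooted language-family trees. Provides anchor detection and coding from
    numeral-form decompositions, continuous-time Markov (Mk-style) models with
    arbitrary transition-rate masks and shared-rate bins, Felsenstein pruning
    likelihoods with ambiguity and polytomy support, reversible-jump MCMC over
    rate configurations, stepping-stone marginal likelihood estimation, Bayes
    factor model comparison, root-state restriction tests, iterative model
    reduction, marginal ancestral state reconstruction, and a seeded synthetic
    data generator for trees and traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
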