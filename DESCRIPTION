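Package: evopath
Title: Pathway Models for the Correlated Evolution of Two Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood pathway models for the joint evolution of two
    binary traits on a time-calibrated phylogeny, in the style of Pagel's
    correlated-evolution framework. Implements the 4-state continuous-time
    Markov model with eight single-trait transition rates, exhaustive
    enumeration and fitting of zero-constrained and equality-constrained
    models, AIC-based model comparison with Akaike weights, marginal
    ancestral-state estimation at internal nodes, and seeded simulators
    (Yule trees, trait evolution) for parameter- and model-recovery
    experiments.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
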