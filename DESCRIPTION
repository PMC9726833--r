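Package: bristlephy
Title: Comparative Phylogenetics of Avian Facial Bristles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of discrete
    avian facial characters (facial bristles) and testing their ecological
    correlates. Provides Mk transition-rate model fitting with AIC-based
    model selection, stochastic character mapping with endpoint-conditioned
    history sampling, a discrete-character analogue of Pagel's lambda,
    taxon-sampling and tree-topology sensitivity analyses, and
    phylogenetically controlled Bayesian (MCMC) mixed models for binary
    (threshold/probit) and Gaussian responses. Includes seeded synthetic-data
    generators (trees, pseudo-posterior tree sets, binary characters with
    recorded true histories, specimen-level ecological datasets) so the whole
    pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    coda,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
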