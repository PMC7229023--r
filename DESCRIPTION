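Package: melanomap
Title: Comparative Phylogenetics and Niche Modelling of Concealed Black
    Skin in Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the repeated evolution of concealed
    (feathered) black skin in birds and its association with ultraviolet
    exposure (Gloger's rule). Implements two-state Mk likelihoods with
    equal-rates and all-rates-different fits and likelihood-ratio model
    selection, marginal ancestral state estimation, stochastic character
    mapping with gain/loss counting, the Fritz-Purvis D statistic for
    binary-trait phylogenetic signal, a penalized phylogenetic logistic
    regression with a likelihood-based R-squared, and a maximum-entropy
    trait-distribution model over gridded environmental layers with
    occurrence thinning, variable contributions, response curves and
    difference maps. A synthetic-data generator (birth-death trees,
    Mk traits with full histories, threshold traits, covariates with
    tunable phylogenetic signal, autocorrelated rasters and biased
    occurrence sampling) provides known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
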