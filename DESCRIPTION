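Package: traitphylo
Title: Bayesian Phylogenetics for Annotated Binary Trait Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian phylogenetic inference and cross-phylogeny comparison
    for binary presence/absence trait matrices such as lexical cognate data
    and material-culture (technology) characters. Implements the binary
    covarion substitution model with strict and relaxed lognormal clocks,
    birth-death and fossilised birth-death tree priors with node- and tip-age
    calibrations, character-level partitions and weights, a
    Metropolis-Hastings sampler over time trees, stepping-stone marginal
    likelihood estimation with Bayes-factor model comparison
    (shared versus separate phylogenies), majority-rule consensus
    summarisation, and a congruence suite (Mantel tests on patristic
    distances, PCA trait projection, Blomberg's K over posterior trees).
    A forward simulator of birth-death time trees and covarion-evolved
    trait matrices, including hierarchical character dependencies and
    punctuated change regimes, supports calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
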