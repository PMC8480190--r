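Package: arcdating
Title: Additive Relaxed Clock Models for Dating Pathogen Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian dating of rooted phylogenies with serially sampled
    (heterochronous) tips under six molecular clock models: the strict clock,
    the classical uncorrelated gamma relaxed clock, and the additive relaxed
    clock, each in a discrete (substitution count) and a continuous (branch
    length) version. The additive relaxed clock models the per-branch
    substitution count as a negative-binomial (or gamma) Levy process, so that
    splitting or merging branches does not change the implied distribution of
    substitutions. Includes a heterochronous coalescent simulator, MCMC
    inference of node dates and clock parameters on a fixed rooted topology,
    reversible-jump selection between strict and relaxed continuous clocks,
    DIC model comparison, a date-randomization test of temporal signal, and
    root-to-tip regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    coda,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
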