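Package: gradeshift
Title: Phylogenetic Grade and Regime-Shift Analysis of Brain Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-methods pipeline for detecting clade-level
    reorganization in allometrically related traits on a phylogeny.
    Implements phylogenetic generalized least squares with maximum-likelihood
    Pagel's lambda and phylogenetic confidence intervals, phylogenetic
    analysis of covariance (grade and slope tests), a Bayesian
    reversible-jump multi-regime Ornstein-Uhlenbeck sampler for locating
    shifts in adaptive optima with per-branch posterior probabilities and a
    signal-to-noise effect size, multiple-variance Brownian-motion ancestral
    state and lineage-rate estimation against a generation-scaled
    constant-rate null, distance-based (Q-mode) between-trait rate
    comparison, and a synthetic-data generator that emulates the joint
    structure of the target data (log-log allometry with planted intercept
    grades and lambda-structured residuals on an ultrametric tree).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
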