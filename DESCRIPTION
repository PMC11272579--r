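Package: goalpursuit
Title: Simulation and Analysis of Incremental Goal-Pursuit Decision Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying commitment and abandonment during incremental
    goal pursuit. Provides a generative task simulator (drifting offer
    schedules with occasional jumps, net-filling blocks, a tree-search based
    block acceptance filter), four behavioural valuation models including a
    Monte-Carlo tree-search planner, logistic choice-model fitting with
    indifference-point (persistence bias) estimation and leave-one-out model
    comparison, synthetic participant cohorts with coupled attention and
    persistence biases, spatial-attention analyses, and voxelwise
    lesion-behaviour mapping with permutation-based cluster correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
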