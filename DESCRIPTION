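Package: seqnav
Title: Learning Models and c-Fos Co-Activation Networks for Sequence-Based
    Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling how rodents acquire sequence-based navigation
    in a landmark-free triple-Y water maze, and for relating learning to
    regional brain activation. Provides a discretized maze environment with
    egocentric actions, four candidate learning agents (model-based
    reinforcement learning over a growing transition graph, model-free
    actor-critic with and without a short action memory, and Bayesian path
    integration), trial-by-trial maximum-likelihood parameter fitting with
    restarted differential evolution, free-running simulation under the
    training protocol with latency-curve model comparison, and a c-Fos
    functional-connectivity stage (density normalization, Spearman correlation
    networks at three confidence tiers, degree/betweenness hub identification
    with leave-one-out robustness, Markov clustering, and parameter-activity
    correlations). A synthetic-data module generates behavioural cohorts and
    density tables with planted structure for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
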