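Package: actinet
Title: Active Inference and Learning in Canonical Rate-Coding Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of two-layer recurrent rate-coding
    neural networks whose activity and delay-modulated Hebbian plasticity
    descend a common cost function, together with the exactly equivalent
    variational Bayesian scheme under a binary-factorised partially
    observable Markov decision process (POMDP) generative model. Provides
    the factorised categorical generative model and its Dirichlet parameter
    posteriors, coordinate-wise free-energy minimisers for hidden states and
    decisions, the canonical network dynamics with risk-modulated plasticity
    and their synaptic fixed points, a numeric dictionary verifying the
    network/Bayes correspondence, maze navigation experiments with a delayed
    binary risk signal, and estimation of implicit priors (firing-threshold
    perturbations) from neural activity with prediction of subsequent
    learning.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
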