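Package: ergmpop
Title: Bayesian Multilevel Exponential Random Graph Models for Populations of Networks
Version: 0.1.0
Authors@R:
    person("Population Networks", "Maintainers", email = "maintainers@ergmpop.org",
           role = c("aut", "cre"))
Description: Fits a Bayesian multilevel exponential random graph model (ERGM)
    to a population of binary undirected networks observed on a common node
    set, with network-level covariates entering through a multivariate
    regression on the per-network ERGM parameters. Inference uses an
    exchange-within-Gibbs sampler that sidesteps the intractable ERGM
    normalising constant via auxiliary network simulation, with an
    ancillarity-sufficiency interweaving strategy (ASIS) and adaptive
    random-walk proposals. Includes posterior-predictive goodness-of-fit
    summaries (degree, geodesic and edgewise-shared-partner distributions),
    generators for synthetic network populations and correlation-matrix
    front ends with degree-targeted thresholding, and a small command-line
    interface for simulate/fit/gof workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
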