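Package: vconn
Title: Virtual Connectome Completion with Whole-Brain Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based completion of missing connectomic data. Given a
    structural connectome (SC), infer a virtual functional connectome (FC)
    with either a stochastic linear model (coupled Ornstein-Uhlenbeck
    processes with closed-form stationary covariance) or a nonlinear
    reduced Wong-Wang mean-field model driven through a Balloon-Windkessel
    hemodynamic stage; given an FC, infer a virtual SC by linear inversion
    or by iterative effective-connectivity fitting. Completion directions
    can be chained into bivirtual duals and expanded into virtual cohorts.
    Includes dynamic functional connectivity (dFC) analysis, weighted graph
    metrics, community comparison, and a synthetic connectome generator so
    every pipeline is testable without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
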