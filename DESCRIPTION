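Package: fcdyn
Title: Functional Connectivity Dynamics of Single-Cell Calcium Imaging Networks
Version: 0.1.0
Authors@R:
    person("fcdyn", "maintainers", email = "fcdyn@example.org", role = c("aut", "cre"))
Description: Resting-state functional-connectivity (FC) analysis of single-cell
    calcium-imaging recordings from cultured neuronal networks. Implements
    baseline subtraction and calcium-event detection, whole-recording FC
    topology with degree-distribution model fitting (Poisson, Binomial,
    power law), sliding-window FC and the time-by-time FC-dynamics (FCD)
    matrix, ICA-based extraction of four correlation patterns per network
    with signed-quartile meta-state discretization, nine FC-dynamics
    summary variables, and a linear mixed-effects group comparison with a
    random intercept per cell line. A synthetic calcium-network simulator
    with planted switching connectivity states and scale-free structural
    topology provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
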