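Package: cmepolicy
Title: Neural Policy Solver for Chemical Master Equation Statistics and
    Sensitivities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates expectations of output functions under the chemical
    master equation (CME) of a stochastic reaction network, together with
    their sensitivities to all model parameters, by training a small neural
    "policy map" against a pathwise martingale identity derived from
    Kolmogorov's backward equation. Trajectories are simulated exactly with
    the modified next reaction method, which yields the per-reaction
    counting processes and their compensators needed by the loss. Ground
    truth for validation comes from finite state projection (forward and
    backward solves via uniformization), exactly-closed moment equations
    for affine-propensity networks, and closed-form birth-death results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
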