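Package: glvdirect
Title: Direct-Transcription Parameter Estimation for Microbial Community
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating growth and interaction parameters of
    generalized Lotka-Volterra (gLV) and saturable gLV models of microbial
    communities from mono-species and pairwise co-culture time series.
    The maximum a posteriori estimation problem is transcribed into a
    sparse algebraic nonlinear program via implicit Euler discretization,
    with Gaussian (L2) or Laplacian (L1) priors, biological parameter
    bounds, and an optional conditional value-at-risk (CVaR) objective
    that tempers the influence of outlying experiments.  The package
    provides a stiff reference simulator with serial-dilution events, a
    synthetic experiment designer and data generator, observability
    diagnostics based on the inertia of the augmented KKT system
    (block-bordered Schur complement elimination and Haynsworth's
    additivity formula), randomized-MAP posterior sampling for
    uncertainty quantification, and fitting-error diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
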