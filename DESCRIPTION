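Package: ffamm
Title: Minimal Models of Glucose and Free Fatty Acid Kinetics in
    Glucose and Meal Tolerance Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for fitting low-dimensional ordinary differential
    equation models of insulin regulation of plasma glucose and free
    fatty acids (FFA) to insulin-modified frequently-sampled intravenous
    glucose tolerance tests (IM-FSIGT) and mixed-meal tolerance tests
    (MT).  Implements three model variants sharing a remote insulin-action
    compartment, empirical log-normal-like and Rayleigh-like meal
    rate-of-appearance (Ra) functions, per-subject weighted least-squares
    estimation with variances obtained by rank-1 singular spectrum
    analysis, spline-based back-calculation of glucose Ra, BIC/RMSE model
    comparison, physiological indices (AIRg, disposition index), and a
    protocol-faithful synthetic-subject generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
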