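Package: doseresp
Title: Nonparametric Tests and Simultaneous Confidence Bands for the
    Causal Dose-Response Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric inference on the causal dose-response function
    for a bounded continuous exposure. Implements a test of the null
    hypothesis that the mean-centered dose-response curve equals a given
    candidate function, based on one-step and targeted minimum loss
    estimation of inner products between the curve contrast and a Sobolev
    eigenbasis, with calibration by a multiplier bootstrap of the supremum
    statistic over a roughness-constrained unit-variance function class.
    Simultaneous confidence bands for the centered curve are obtained by
    inverting the test over a smoothness-constrained candidate class with
    a fixed-multiplier closed-form approximation. Includes a synthetic
    data generator for a confounded continuous-exposure design and a
    Monte Carlo harness for size, power, and band-coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
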