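Package: dacue
Title: Analysis of Value-Coded Dopamine Cue Responses and Conditioned Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing midbrain dopamine (DA) neuron spike trains and
    conditioned behavior recorded in Pavlovian visual-conditioning sessions
    with a pre-injection control block and a superior-colliculus inactivation
    block. Provides spike density function estimation, windowed response
    magnitudes, two response-latency detectors (a 2-SD baseline crossing and a
    sign-test value-differentiation onset), exact small-sample Wilcoxon
    signed-rank and sign tests, permutation tests, conditioned-licking
    discrimination statistics, saccade-latency prolongation analysis,
    DA-neuron screening criteria, and an inhomogeneous-Poisson synthetic
    session generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
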