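Package: drex
Title: Dynamic Regularity Extraction from Tone Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Online Bayesian prediction over tone sequences with unknown
    changepoints. Lagged tone vectors within a statistical context are
    modelled as D-variate Gaussian under a conjugate Normal-Inverse-Wishart
    prior; a run-length posterior over context lengths is maintained with a
    constant changepoint hazard, and the context-integrated Student-t
    predictive yields a per-tone surprisal trace. Includes working-memory and
    observation-noise constraints, seeded generators for classic auditory
    deviance-detection paradigms (oddball, roving, pattern, predictability,
    biased-context, Gaussian-context, regular/random), a replication harness
    with the standard statistical summaries, and an exact changepoint
    enumeration oracle for validating the recursion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
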