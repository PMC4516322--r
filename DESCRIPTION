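Package: gapdetect
Title: Gap-in-Noise Detection Psychophysics: Psychometric Fitting,
    Signal Detection Measures, and Latency Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gap-in-noise detection behavior in
    operant tasks (ferret and human variants). Builds per-session
    percent-gap functions anchored by the no-gap false-alarm rate, fits a
    right-weighted Gumbel sigmoid with guess and lapse parameters by
    maximum likelihood under the midpoint/width ("mw") parameterization,
    gates fits with a parametric deviance bootstrap, and transforms fitted
    curves to d-prime space to extract detection threshold (gap length at
    d' = 1), slope at threshold, lapse rate, and asymptote sensitivity.
    Also provides ex-Gaussian maximum-likelihood fitting of response-time
    distributions, rule-based extraction of head-orienting turns from
    60 frames/s bearing traces, shuffle-and-resample significance testing
    of Spearman correlations, and a synthetic observer that simulates
    trial schedules, latencies, and head trajectories for parameter-
    recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
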