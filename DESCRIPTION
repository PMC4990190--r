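Package: diplacusr
Title: Simulation and Analysis of Binaural Pitch Diplacusis Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and analysing binaural pitch diplacusis,
    the perceptual anomaly whereby the same tone evokes a different pitch in
    the left and right ears of one listener. Provides virtual 2AFC observers
    with asymmetric hearing loss and interaural pitch maps, simulators for
    the maximum-comfort-level ascent, adaptive one-down/one-up interaural
    loudness balancing and fixed-grid interaural pitch-comparison protocols,
    binomial-logistic psychometric fitting with point-of-subjective-equality
    (PSE) extraction, Bayesian credible intervals for PSE shifts via MCMC,
    normative classification, and cohort-level statistics (shift-asymmetry
    correlation with leave-one-out influence diagnostics, log-slope group
    comparison, prevalence tabulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
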