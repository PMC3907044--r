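Package: trafficsem
Title: Bayesian Structural Equation Models for Latent Traffic Pollution
    and Cardiac Autonomic Tone
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying short-term effects of traffic-related air
    pollution on heart rate variability (HRV) in repeated-measures cohort
    designs. A latent traffic-pollution exposure is measured by black
    carbon, carbon monoxide, nitrogen monoxide and nitrogen dioxide, and a
    latent cardiac parasympathetic tone is measured by log-transformed HF
    power, SDNN and rMSSD; the sympathetic balance marker log LF/HF is
    modelled directly. The package provides a synthetic cohort generator
    with the exact generative structure the model assumes, exposure
    preprocessing (multi-station averaging, pre-visit moving averages,
    apparent temperature, seasonal adjustment and temperature
    residualization), a blocked Gibbs sampler for the structural equation
    model with subject-level random intercepts and effect-modification
    interactions, a comparison Bayesian linear mixed model with a
    frequentist REML oracle, and reporting of percent change per
    interquartile-range increase in exposure with posterior intervals and
    directional posterior probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
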