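Package: mcia
Title: Multi-Component Information Accumulation Modelling of Perceptual
    Information Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dilution effect in perceptual decision
    making with the Multi-component Information Accumulation (McIA) model, a
    biased random walk that samples evidence from the top half, the bottom
    half, or the optimally (odds-product) combined whole of a morphed face
    stimulus.  Provides the face-categorization experiment design (morph
    arithmetic, calibration-level interpolation, test-face enumeration, block
    construction), a simulated 2-up-1-down staircase calibration against
    synthetic psychometric observers, closed-form gambler's-ruin choice and
    response-time predictions for several model variants, weighted
    least-squares model fitting by Nelder-Mead with multi-start, the
    trial-level behavioral pipeline (filtering, accuracy coding, deviation
    scores, condition summaries, strength-difference and median-split
    analyses), and a Monte-Carlo generator of synthetic experiments with
    configurable contamination for oracle validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
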