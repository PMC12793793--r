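Package: thetamod
Title: Frontocentral Band Power and Modulation Indices for Infant EEG
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies infant frontocentral band activity from continuous
    EEG: absolute band power (log-domain band-integrated power spectral
    density), relative band power, and a modulation index (Pearson
    correlation of per-second band power with time) for the infant theta
    (3-6 Hz) and alpha (6-9 Hz) bands. Implements the preprocessing the
    indices depend on (zero-phase FIR band-pass filtering, 1-second
    segmentation, amplitude- and gaze-based epoch rejection, a
    minimum-clean-segment inclusion gate), split-half and mixed-model
    intraclass-correlation reliability and longitudinal stability analyses,
    and an outcome-prediction stage built on composite standardized scores,
    stepwise AIC model selection, collinearity diagnostics and standardized
    coefficients. A synthetic generator produces 1/f-background EEG with
    ramping narrowband oscillations, gaze annotations and longitudinal
    cohort tables with known ground truth, so every stage is testable
    without recorded data. Includes minimal readers and writers for
    European Data Format and BrainVision Core recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    car
Config/testthat/edition: 3
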