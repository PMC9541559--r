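Package: phonopress
Title: Modeling and Estimation of Vocal Fold Collision Pressures During
    Phonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying intraglottal, subglottal, and vocal fold
    collision pressures during phonation. Provides a self-oscillating
    three-mass body-cover model of the vocal folds with muscle-activation
    rules, a synthetic multichannel recording generator that emulates in
    vivo pressure-probe acquisition (hydrostatic calibration, DC drift,
    16-bit quantization), the measurement procedures used with such
    recordings (calibration fitting, zero-offset correction, cycle
    detection, per-cycle peak collision pressure, autocorrelation
    fundamental frequency, sound pressure level, strike-zone waveform
    criteria, sensor co-location testing), a Hertzian contact-pressure
    analysis of vocal fold edge kinematics, and an extended Kalman filter
    that estimates subglottal pressure, posterior glottal opening, muscle
    activations, and collision pressure from the glottal area waveform as
    the only observation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
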