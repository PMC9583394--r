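Package: sonimlp
Title: Adaptive Just-Noticeable-Difference Measurement for Two-Dimensional Sonification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Runs and simulates a standardized adaptive two-alternative
    forced-choice (2AFC) experiment, based on the maximum likelihood
    procedure (MLP), for the perceptual evaluation of two-dimensional
    sonifications. Models the normalized [-1,1]^2 mapping space with its
    quadrant standards, maintains a grid of logistic psychometric
    hypotheses whose likelihoods are updated after every trial, places
    each stimulus at the sweet point of the best hypothesis, and reads
    out a just-noticeable difference (JND) per track. A parameterized
    virtual observer enables closed-loop simulation and parameter
    recovery without human subjects. JNDs are turned into standardized
    perceptual-resolution, hysteresis, and perceptual-interference
    scores and report tables, and variable stimulus grids can be
    rendered to WAV through a user-supplied sonifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
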