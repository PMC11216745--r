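Package: cdjsdm
Title: Context-Dependent Joint Species Distribution Models for
    Camera-Trap Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits context-dependent joint species distribution models
    (latent-factor multivariate probit models whose factor loadings are
    linear functions of disturbance covariates) to camera-trap
    presence-absence data, and derives disturbance-dependent residual
    association matrices with credible intervals. Includes the
    surrounding camera-trap workflow: independence filtering of
    detections, covariate standardisation, solar-time diel activity
    classification, nocturnality shift tests, bootstrap contrasts of
    time-to-encounter between species pairs, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
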