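Package: impactkit
Title: Head Impact Detection from Instrumented-Mouthguard Kinematics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects helmeted head impacts from triggered six-degree-of-freedom
    instrumented-mouthguard recordings. Provides anatomical-frame signal
    preprocessing (rotation, zero-phase Butterworth filtering, trapezoid
    integration, five-point-stencil differentiation), a canonical 411-feature
    registry spanning time-domain, power-spectral-density, Morlet-wavelet and
    head-neck linkage-model features, infrared device-placement thresholding by
    a two-component Gaussian mixture, video-label ground-truth construction
    rules, and a radial-basis-function support vector machine trained with
    sequential forward feature selection under leave-one-out cross-validation,
    together with ROC/precision-recall evaluation, feature-screening
    statistics, and a seeded synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
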