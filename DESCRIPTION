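Package: gaitwork
Title: Joint Work, Partial Least Squares Regression and Paired Statistics
    for Running Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying fatigue-induced changes in
    sagittal-plane running joint mechanics. Provides a synthetic generator of
    paired pre/post-fatigue stance-phase waveform cohorts calibrated to
    published population summaries, zero-phase Butterworth signal
    conditioning, 30 N ground-reaction-force stance detection and 101-point
    time normalization, joint power and positive/negative/total joint work by
    trapezoidal integration, a from-scratch NIPALS partial least squares
    regression with leave-one-out PRESS/Q-squared component selection, a
    tabulated one-predictor-at-a-time perturbation sensitivity analysis, and
    paired pre/post statistics including a permutation-based whole-stance
    waveform test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    mixOmics,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
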