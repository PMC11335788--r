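Package: plrconv
Title: Convolution Modeling of Pupil Size Responses to Dynamic Visual Input
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts luminance-change and contrast-change events from video
    frame sequences (optionally gaze-contingent and resolved per visual-field
    region), convolves them with gamma-family pupil response functions, and
    fits the resulting linear time-invariant model to continuous pupil
    recordings by Nelder-Mead simplex search with repeated cross-validation.
    Includes event-related benchmark pipelines (polynomial fit, two-LTI
    epoch model, binned contrast-response model) and a synthetic
    stimulus/recording generator with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
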