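Package: swirpupil
Title: Closed-Eye Pupillometry and Gaze Estimation from Short-Wave Infrared Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the pupillary light reflex (PLR) and gaze
    direction through closed eyelids from short-wave infrared (SWIR) video.
    Implements the fixed-circle darkness measurement with blink removal and
    zero-phase low-pass filtering, stimulus-locked epoching and robust-PLR
    statistics, a linear darkness-to-diameter calibration, pupil-position
    based gaze estimation in degrees of visual angle with a segment-shuffle
    surrogate test, and a small convolutional encoder-decoder that
    reconstructs open-eye frames from closed-eye frames. A seeded synthetic
    session generator emulates the optical and statistical structure of
    closed-eye SWIR recordings (PLR kinetics, eyelid attenuation and blur,
    blink transients, 3x3-grid fixations, a forehead control region) and
    provides ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
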