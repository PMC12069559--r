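Package: laryngovibro
Title: Laryngovibrogram Analysis of Vocal Fold Vibration from Segmented High-Speed Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the Laryngovibrogram (LVG), a normalized spatiotemporal
    representation of vocal-fold vibratory dynamics, from per-frame 4-class
    label masks (background, glottis, right and left vocal fold) of laryngeal
    high-speed video. Tracks the posterior landmarks and anterior commissure,
    derives the per-fold vibrational axes and the glottal opening angle,
    computes signed length-normalized fold-edge deflections resampled to 256
    positions per fold, and concatenates them over time into the LVG matrix.
    Provides the Phonovibrogram baseline, quantitative vibratory measures
    (relative normalized deflection, shimmer, jitter, amplitude-symmetry
    quotient, lateral phase difference via complex Morlet wavelet phase),
    voice-onset segmentation with opening-angle regression, and a synthetic
    kinematics generator that produces label-mask sequences with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
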