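Package: mibci
Title: Motor-Imagery EEG Classification by Time-Frequency Image
    Subtraction and an Attention CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-class (left vs. right hand) motor-imagery
    EEG classification from the C3/C4 electrode pair.  Trials are
    band-pass filtered (8-30 Hz), converted to Morlet-wavelet
    time-frequency power maps, and the C3 and C4 maps are combined
    into a single 64x64 classifier image either by pixel-wise
    subtraction (exploiting the lateralized ERD/ERS contrast) or by
    vertical stacking.  A compact convolutional network with a
    convolutional block attention module (channel and spatial
    attention) classifies the images; it is trained with Adamax and
    evaluated by repeated stratified 10-fold cross-validation with
    accuracy and Cohen's kappa.  A synthetic ERD/ERS trial simulator
    (lateralized mu/beta band-power modulation over 1/f noise) makes
    the whole pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
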