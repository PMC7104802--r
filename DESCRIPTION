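Package: tfhfo
Title: Computer-Vision Detection of High-Frequency Oscillations on
    Time-Frequency Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised detection of high-frequency oscillations (HFOs,
    ripples and fast ripples) in single-channel intracranial EEG. Signals
    are transformed to Morlet continuous-wavelet time-frequency maps, which
    are processed as grayscale images: a geometric schedule of intensity
    saturation levels, suppression of border-connected structures by
    grayscale morphological reconstruction, Otsu binarization, and
    connected-component blob analysis yield HFO candidates that are
    validated against frequency-band, duration and amplitude criteria.
    Includes a closed-form analytic model of spikes and Gaussian-envelope
    HFOs with their frequency spectra, a simulation benchmark mixing an
    HFO train with pink noise at fixed signal-to-noise ratios, and an
    evaluation harness computing sensitivity, positive prediction value,
    F-measure and localization errors against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
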