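Package: pcgLVDD
Title: Heart-Sound Analysis for Left-Ventricular Diastolic Dysfunction Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Phonocardiogram (PCG) analysis pipeline for screening left
    ventricular diastolic dysfunction (LVDD) from heart sounds: synthetic PCG
    simulation with ground-truth state labels, resampling and wavelet
    denoising, four-state heart-sound segmentation with a duration-constrained
    hidden semi-Markov model, short-time Fourier transform spectrogram
    imaging, non-generative audio augmentation and DCGAN-based spectrogram
    augmentation, a compact convolutional network classifier with subject-wise
    cross-validation, and a train-on-generated/test-on-real similarity
    protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    nnet,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
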