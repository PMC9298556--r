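Package: eegsent
Title: Spectral-Entropy Heat Maps and Compact Convolutional Networks for EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-class diagnostic classification of multichannel
    resting-state EEG via normalized spectral-entropy heat maps. Continuous
    16-channel recordings are band-pass filtered, segmented into overlapping
    4-second epochs, and each epoch channel is converted into a 17x17
    time-by-frequency-band image of normalized Shannon spectral entropy
    (or band power as a control representation). Two compact convolutional
    network architectures -- a plain two-convolution baseline and an
    inception-style optimized variant with a channel-mixing 1x1 input
    convolution -- are reconstructed declaratively with exact shape inference
    and learnable-parameter counting, and trained with a built-in
    Adam/early-stopping engine under 10-fold cross-validation. Channel
    importance is scored from the absolute 1x1 kernel weights across folds.
    A seeded synthetic EEG cohort generator with class-dependent spectral
    complexity makes the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
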