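Package: whaledet
Title: Humpback Whale Call Detection from Passive Acoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting humpback whale calls in
    passive acoustic monitoring audio. Standardizes PCM WAV recordings, cuts
    them into overlapping six-second analysis windows, renders log-power mel
    spectrogram and delta-MFCC feature images, applies stochastic waveform
    augmentation with a rejection rule, assigns whole recordings to
    train/validation/test splits to prevent temporal leakage, and trains two
    compact vision classifiers (a four-block convolutional network and a
    patch-embedding vision transformer) implemented natively with an AdamW
    optimizer, warm-up plus cosine learning-rate schedule, early stopping and
    checkpointing. Includes a full evaluation suite (confusion matrix,
    per-class precision/recall/F1, Matthews correlation, class-conditional
    error rates, ROC and precision-recall curves) and a synthetic bioacoustic
    corpus generator for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    signal,
    jsonlite,
    yaml,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    png
Config/testthat/edition: 3
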