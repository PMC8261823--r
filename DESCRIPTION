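Package: nystagmusdetect
Title: Detection of Positional Nystagmus in Wearable Electrooculography
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A frame-level detection pipeline for benign paroxysmal
    positional vertigo (BPPV) nystagmus in dual-rate wearable recordings
    (two electrooculography channels plus a three-axis accelerometer).
    Provides Butterworth high-pass drift removal and accelerometer
    resampling, sliding-window feature framing with per-row unit
    normalisation, SMOTE class balancing, an ensemble of small seeded
    convolutional networks fused by majority vote, run-length (sieve)
    post-processing, and the frame-level cross-fold evaluation protocol,
    together with a synthetic recording simulator that emulates the
    statistical structure of clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
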