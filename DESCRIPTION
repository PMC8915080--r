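Package: emgtcn
Title: Temporal Convolutional Networks for Surface EMG Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence classification of multichannel surface electromyography
    (sEMG) recordings with temporal convolutional networks (TCNs): causal
    dilated convolutions arranged in residual blocks, with either
    average-over-time or attention pooling heads. Includes the signal
    augmentation operators used for small sEMG training sets (wavelet-domain
    perturbation, magnitude warping, additive Gaussian noise at a target SNR),
    repetition-based intra-subject evaluation with class-weighted top-k
    metrics, a real-time simulation harness that streams 200 ms segments
    through a trained model, a threshold-vote post-classifier with timing
    analytics and (window, threshold) grid search, and a seeded generator of
    Ninapro-DB1-structured synthetic sEMG so the full pipeline is testable
    without data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
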