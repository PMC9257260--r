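Package: eegdann
Title: Brain-Connectivity Features and a Domain-Adversarial Residual
    Convolutional Network for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Constructs functional brain-connectivity feature matrices
    (Pearson correlation, phase-locking value, transfer entropy, wavelet
    coherence) from windowed multichannel EEG, arranges their rows and
    columns by scalp-distance or one-dimensional-scaling electrode
    orderings, and classifies binary valence/arousal emotion labels with a
    residual convolutional network trained adversarially against a domain
    discriminator through a gradient-reversal layer. Includes within-subject
    and leave-one-subject-out cross-validation protocols, an ablation
    harness over feature/adaptation variants, and a synthetic multi-subject
    EEG generator with class-dependent inter-channel coupling and
    per-subject domain shift so the whole pipeline is testable without
    access to restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
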