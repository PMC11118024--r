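Package: fatiguegan
Title: EEG Fatigue Detection with an Attention-Based Auxiliary-Classifier GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects driver fatigue from multi-channel EEG using a
    space-frequency-time differential-entropy feature tensor and an
    auxiliary-classifier Wasserstein GAN with gradient penalty. Raw
    recordings are trimmed, resampled and cut into 8-second segments;
    five-band differential entropy per half-second frame is mapped onto a
    2D electrode grid to form 4D features. The generator and discriminator
    share spatial/frequency squeeze-excitation attention, inverted
    bottleneck residual convolutions and a Transformer encoder over time
    frames; the discriminator carries a Wasserstein critic head and a
    class head. Includes PERCLOS-based labelling, wavelet-coherence
    similarity scoring between real and synthetic signal sets,
    confidence-based selection of generated samples, training-set mixing
    experiments, stratified cross-validation, and a seeded synthetic EEG
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
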