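Package: ecgbeats
Title: Residual-Dense Convolutional Networks for Five-Class ECG Heartbeat
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for beat-level electrocardiogram (ECG)
    arrhythmia classification into the five standard heartbeat classes
    (normal, supraventricular premature, premature ventricular contraction,
    fusion, unclassifiable). Provides a synthetic five-class beat generator
    with a realistic noise taxonomy (Gaussian noise, baseline wander,
    powerline interference, motion bursts, contact loss); a denoising
    preprocessor (gap interpolation, running-median baseline removal,
    zero-phase IIR notch filtering, wavelet shrinkage, per-beat
    z-normalisation); class-imbalance resampling and stratified data
    partitioning; a residual-dense one-dimensional convolutional network
    trained with Adam and early stopping, implemented natively including
    backpropagation; penultimate-layer feature extraction feeding a
    one-versus-all support vector machine; and an evaluation suite
    (accuracy, sensitivity, specificity, precision, F1, Cohen's kappa,
    one-versus-rest AUC) with tidy accessors and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
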