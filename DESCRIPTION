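Package: carsdenoise
Title: Deep-Learning Denoising and Equivalent Imaging Rate Estimation for
    Scanned Laser Nerve Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for improving the effective imaging rate of low
    signal-to-noise scanned laser (CARS) nerve imaging by deep-learning
    noise reduction. Provides a synthetic nerve-phantom and frame-by-frame
    acquisition simulator (signal-dependent shot noise, detector read
    noise, sparse impulse events, frame averaging), three compact
    convolutional denoiser architectures built from a (filters, kernel,
    layers) triple, a training pipeline with patch augmentation,
    pre-train/fine-tune transfer and four-model ensembling, image quality
    metrics (PSNR, SSIM), the Equivalent Imaging Rate (EIR) computed from
    metric-versus-rate curves, and a nested cross-validation evaluation
    harness with Friedman, paired t and Bonferroni-Holm statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
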