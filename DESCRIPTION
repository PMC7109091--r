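Package: mrcnn
Title: Multi-Resolution Convolutional Networks for Image-to-Image Inverse Problems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains multi-resolution convolutional neural networks
    (a U-Net whose decoder stages emit additional coarse outputs supervised
    against area-averaged copies of the target) for image-to-image inverse
    problems such as phase retrieval from defocus series and low-dose
    scanning transmission electron microscopy denoising. Includes the
    synthetic forward models needed to generate training data without any
    external download (Fresnel wave propagation, annular dark-field atomic
    image synthesis, compound Poisson/Gaussian/uniform/clipping noise,
    inverse-Laplacian toy pairs), a hand-crafted low-pass-filter input
    layer, mean-absolute-error training with deep multi-scale supervision,
    optional conditional-adversarial fine-tuning, and evaluation metrics
    (MAE, SNR in decibels, Fourier ring correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
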