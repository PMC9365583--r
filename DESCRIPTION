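Package: ctdenoise
Title: Low-Dose CT Denoising with a Residual Dense Encoder-Decoder and a
    Mask-Guided Correction Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements an encoder-decoder convolutional network for low-dose
    computed tomography (LDCT) slice denoising, built from improved residual
    dense blocks, and trains it with a two-phase schedule in which a binary
    mask derived by thresholding the prediction-minus-target difference image
    selects hard regions for an additional correction loss. The training
    objective is a weighted sum of mean squared error, multi-scale structural
    similarity (MS-SSIM) and a high-pass gradient loss. Includes a
    seed-deterministic CT phantom simulator (random ellipse phantoms,
    line-integral projection, Poisson photon statistics at a configurable dose
    fraction, ramp-filtered backprojection) that produces paired
    low-dose/normal-dose slices for testing, plus PSNR/SSIM evaluation,
    threshold-selection scans, and simple image/config I/O. The convolutional
    layers and reverse-mode gradients are implemented in the package (Rcpp),
    so no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
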