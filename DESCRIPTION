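Package: dwiunroll
Title: Self-Supervised ADMM-Unrolled Reconstruction for Multi-Shot Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scan-specific, self-supervised ("zero-shot") reconstruction of
    multi-band multi-shot diffusion-weighted EPI by unrolling the alternating
    direction method of multipliers (ADMM) with a learned convolutional
    regularizer, trained on a single multi-band slice by disjoint k-space
    mask splitting. Includes the SENSE-type encoding operator with shot-phase
    and CAIPI multi-band terms, classical comparators (MUSE-style Tikhonov
    reconstruction, locally-low-rank ADMM), a self-gated shot-to-shot phase
    estimator, a synthetic multi-coil k-space simulator with known ground
    truth, and evaluation utilities (PSNR, SSIM, NRMSE, diffusion tensor
    fitting with FA/cFA maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
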