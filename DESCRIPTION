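Package: dualreg
Title: Unsupervised Dual-Network Registration of Serial-Section Electron Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable registration of serial-section electron microscopy
    image pairs with a two-stage dual network: a small convolutional encoder
    (LinearNet) regresses the six parameters of a global affine deformation
    from a low-resolution pair, and a shallow encoder-decoder (NonlinearNet)
    regresses the residual dense displacement field from the affinely warped
    pair. Both stages are trained jointly and unsupervised from image-space
    losses (L1 intensity, patchwise structural similarity, an affine
    near-identity constraint and first/second-order field smoothness)
    through a differentiable bilinear warping layer. Includes a synthetic
    deformation generator (random affine plus thin-plate-spline fields over
    neuron-like textures), SSIM and region-overlap Dice evaluation metrics,
    an ablation harness, and plain-file input/output for images, labels and
    displacement fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    generics,
    jsonlite,
    png,
    tiff,
    tibble,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
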