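Package: deformreg
Title: Unsupervised Deformable Registration of 3D Brain MRI with
    Convolutional U-Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable image registration for skull-stripped 3D brain MR
    volumes using an unsupervised convolutional encoder-decoder that
    predicts a dense voxel displacement field, a differentiable trilinear
    warping layer, and a loss combining negative local normalized
    cross-correlation with a diffusion smoothness penalty. Includes NIfTI
    input/output and preprocessing (crop, resize, intensity
    normalization, dataset splitting), VoxelMorph-1/2 baseline network
    builders, Dice/SSIM/endpoint-error evaluation, and a synthetic brain
    phantom generator with known ground-truth deformations so the whole
    pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
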