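Package: ecgan
Title: Self-Supervised 3D Adversarial Electronic Cleansing for CT Colonography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Electronic cleansing (EC) of contrast-tagged residual fluid from
    CT colonography volumes with a three-dimensional image-to-image
    conditional adversarial network. A 3D U-Net generator and PatchGAN
    discriminator are pre-trained on registered clean/tagged volume-of-interest
    pairs from a digital colon phantom, then fine-tuned per case by a
    self-supervised loop that iteratively regenerates its own training targets
    with the evolving generator. Includes a digital colon-phantom simulator
    with ground-truth fluid masks and centerlines, volumetric I/O (NIfTI and
    MetaImage) with Hounsfield-unit normalisation, centerline-based VOI
    extraction, tiled whole-volume inference, and PSNR-based evaluation with
    paired t-tests. The volumetric convolution engine (forward, backward,
    Adam) is implemented in the package on top of compiled im2col/col2im
    kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
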