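Package: virtmihc
Title: Virtual Multiplexed Immunostaining of Label-Free Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conditional adversarial virtual staining of label-free
    autofluorescence microscopy tiles. A single generator maps 4-channel
    autofluorescence images plus a constant digital staining matrix (DSM)
    channel to brightfield-equivalent H&E, ERG or PanCK images; training
    uses a registration-in-the-loop displacement network that absorbs
    residual misalignment between network output and chemically stained
    ground truth before the pixel-wise loss. Includes a tissue-phantom
    simulator producing co-registered autofluorescence/brightfield pairs
    with known ground truth, a quantitative evaluation suite (PSNR, SSIM,
    perceptual distance, DAB colour-deconvolution nuclei quantification,
    down-sampled IoU), tiled whole-field inference, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    png,
    jsonlite,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
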