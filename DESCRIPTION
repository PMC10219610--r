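Package: ettseg
Title: Endotracheal Tube Segmentation and Tip Localization with Compound
    Loss Functions and U-Net++
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for segmenting thin curvilinear tubes (such as an
    endotracheal tube on a chest radiograph) and localizing the tube tip.
    Implements six single segmentation losses (binary cross-entropy, focal,
    Matthews correlation coefficient, Dice, Jaccard, Tversky) and the nine
    compound distribution-plus-region combinations; a configurable U-Net++
    segmentation network with nested dense skip connections, optional deep
    supervision and pluggable encoders, trained by hand-derived
    backpropagation over compiled convolution kernels; max-pool downscaling,
    center cropping and flip/affine/CLAHE augmentation; tube-tip extraction
    with IOU, Euclidean tip-distance and percentage-of-samples-within-error
    (PSE) evaluation; a synthetic radiograph-like tube-phantom generator; and
    a k-fold cross-validation harness comparing losses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
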