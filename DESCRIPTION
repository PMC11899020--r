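Package: cervseg
Title: Dual-Encoder Attention Segmentation of Colposcopic Lesion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semantic segmentation toolkit for acetowhite lesion delineation in
    colposcopic images of the uterine cervix. Implements a dual-encoder
    U-shaped network that fuses residual-style and depthwise-separable-style
    feature pyramids, squeeze-and-excitation channel attention on skip
    connections, a lightweight atrous spatial pyramid pooling context block,
    and a hybrid Dice plus Tversky loss for class-imbalanced lesions, together
    with LabelMe-dialect polygon annotation rasterization, dataset
    preparation (resizing, augmentation, stratified splitting, proportional
    expansion), a six-metric evaluation suite (pixel accuracy, mean pixel
    accuracy, mean IoU, frequency-weighted IoU, Dice, Hausdorff distance)
    plus Cohen's kappa, Grad-CAM++ explainability heatmaps, and a synthetic
    phantom generator providing exact ground truth for end-to-end testing.
    Includes a self-contained double-precision convolutional network engine
    (im2col convolutions, transposed and depthwise convolutions, batch
    normalization, reverse-mode automatic differentiation, Adam).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
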