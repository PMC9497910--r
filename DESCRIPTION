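Package: cytofcn
Title: Tile-Based Fully Convolutional Segmentation of Cytology Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of metastatic tumor cells in gigapixel
    cytology whole-slide images (WSIs), as produced by rapid on-site evaluation of
    endobronchial-ultrasound-guided transbronchial needle aspiration (EBUS-TBNA)
    smears. A pyramidal slide is decomposed into a patch-based hierarchical tile
    structure, background tiles are discarded by Otsu thresholding on a coarse
    pyramid level (tiles with less than 70% tissue are dropped), and the surviving
    512x512 tiles are classified per pixel into background / benign / malignant by
    a single-stream 32-pixel-stride fully convolutional network whose layers are
    implemented natively (convolution, ceiling-mode max-pooling, dropout,
    bilinear-initialised transposed convolution) with seeded stochastic gradient
    descent training. Tile class maps are stitched into a slide-level class map and
    tumor segmentation. Includes pixel-level evaluation metrics (precision,
    sensitivity, Dice, IoU), slide-level data splits with k-fold cross-validation,
    Fisher's least-significant-difference post-hoc comparison, and a synthetic
    pyramidal-slide generator with ground-truth masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
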