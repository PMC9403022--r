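Package: epistroma
Title: Epithelium/Stroma Segmentation and Quantification for H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Whole-slide image analysis pipeline for hematoxylin and eosin
    stained histology: automatic tissue region-of-interest detection
    (downsampling, CIELAB chroma K-means, largest-connected-component
    bounding box), fixed-size tiling with a background-discard rule, a
    dilated-convolution encoder-decoder segmentation network with
    sub-pixel multi-channel upsampling (trained by cross-validated SGD),
    stitching of patch predictions into a global epithelium/stroma mask,
    tissue-ratio quantification with a full confusion-matrix metric
    suite, and downstream Spearman correlation of tissue ratios with
    gene expression followed by hypergeometric over-representation
    analysis of gene sets. Includes synthetic slide, patch, expression
    and gene-set generators with known ground truth so the entire
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
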