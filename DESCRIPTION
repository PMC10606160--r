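Package: dicentricAssay
Title: Automated Dicentric Chromosome Assay by One-Stage Object Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for automating the dicentric chromosome
    assay (DCA), the cytogenetic biodosimetry method that estimates absorbed
    radiation dose from the per-cell frequency of dicentric chromosomes in
    Giemsa-stained metaphase spreads. Provides a synthetic metaphase image
    generator with exact ground truth, automatic bounding-box labeling of
    chromosomes by Otsu thresholding and connected components, copy-paste
    augmentation of segmented chromosome patches to rebalance the rare
    dicentric class, a compact anchor-based one-stage detector (grid/anchor
    box encoding, CIoU location loss, binary cross-entropy objectness and
    class losses, k-means anchor estimation with IoU distance, non-maximum
    suppression) trained by stochastic gradient descent, detection
    evaluation (precision, recall, F1-confidence curves, average precision,
    mAP, chromosomes per metaphase), and linear-quadratic dose-response
    fitting with inverse dose estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    Rcpp,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
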