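Package: gene2image
Title: Class-Discriminative 2D Image Representations of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms one-dimensional gene-expression profiles into
    class-discriminative two-dimensional images and classifies them with a
    convolutional neural network. Genes are ranked by the Fisher distance
    between classes, binned into equal-count categories, selected by
    L1-penalised (LASSO) regression, embedded in the plane by a
    category-supervised linear discriminant analysis, enclosed in a
    minimum-area rectangle (rotating calipers over the convex hull), rotated
    to axis alignment and rasterised onto a pixel grid with collision
    averaging. Per-sample images are then classified by a six-layer CNN
    trained with Adam. Includes a synthetic expression-data generator with
    ground truth for end-to-end validation, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
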