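Package: mammocross
Title: Bilateral Four-View Mammogram Classification with Cross-Breast
    Attention and Patch Contrastive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for per-breast cancer classification from
    bilateral four-view screening mammograms (left/right cranio-caudal and
    mediolateral-oblique views). Includes breast-region detection and
    contrast preprocessing (Gaussian smoothing, Otsu segmentation, CLAHE,
    percentile-truncated normalization), case assembly with scenario
    upsampling and balanced patient sampling, a shared stride-32
    convolutional feature extractor, a cross-mammogram dual-pathway
    multi-head attention module that matches each breast's local features
    against the contralateral breast's global features, a bilateral
    patch-wise contrastive joint loss, dual classification heads trained
    with a weighted joint objective, ROC/AUC evaluation, Grad-CAM
    explanations, and a synthetic-phantom generator so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
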