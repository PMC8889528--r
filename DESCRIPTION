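Package: ctcfish
Title: Rule-Based and Convolutional Identification of Circulating Tumor
    Cells in imFISH Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for identifying circulating tumor cells (CTCs) in
    three-channel immunofluorescence in-situ hybridization (imFISH)
    micrographs (DAPI nuclear stain, CEP8 centromeric probe, CD45
    leukocyte stain). Provides nucleus segmentation by a
    gradient/morphology pipeline, CEP8 spot counting with a rule-based
    CTC caller (DAPI+/CD45-/CEP8>=3), a small convolutional neural
    network classifier with a transfer-learning initialization path,
    imbalance-aware evaluation (stratified splitting, majority-class
    down-sampling, stratified k-fold cross-validation, ROC/AUC,
    confusion-matrix metrics), and a synthetic imFISH image generator
    with complete ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
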