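Package: BitewingCaries
Title: Tooth Detection and Approximal Caries Severity Classification in
    Bitewing Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for assessing approximal caries severity
    on bitewing dental radiographs. Individual tooth regions are located by
    contrast-limited adaptive histogram equalization, Otsu thresholding and
    morphological refinement; cropped teeth are class-balanced by flip and
    small-angle rotation augmentation and classified into three severity
    stages (normal, incipient, advanced) by a compact convolutional network
    trained with momentum SGD. The evaluation suite computes one-vs-rest
    precision, recall, specificity, negative predictive value and
    Mann-Whitney ROC AUC from 3x3 confusion matrices, counts predicted
    lesions per exam, compares raters with Wilcoxon signed-rank tests, and
    solves the noncentral-t power equation for paired-design sample sizes.
    A phantom generator renders synthetic bitewing-like images with exact
    ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Segmentation, Preprocessing
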