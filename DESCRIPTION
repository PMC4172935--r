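Package: hippovol
Title: Hippocampal Volumetry and Ensemble Classification for Structural Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Threshold-based grey-matter/white-matter/CSF volumetry and
    rectangular-ROI hippocampus extraction from spatially normalized coronal
    brain slices, with a majority-voting ensemble of three classifiers (RBF
    support vector machine, small multilayer perceptron, pruned decision tree)
    evaluated by stratified ten-fold cross-validation. Ships a synthetic
    brain-slice phantom generator with known ground truth so the whole
    pipeline is testable without access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
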