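Package: petqc
Title: Automated Clinical Image-Quality Scoring for Low-Count Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts clinician-style image-quality scores (global quality
    rating, pattern recognition, diagnostic confidence; 0-3 scale in 0.5
    steps) for low-count positron emission tomography reconstructions using
    a small VGG-style convolutional regression network trained on 2-D image
    patches. Includes a synthetic brain-phantom cohort generator with
    image-space count thinning and count-dependent resolution loss, patch
    extraction with background thresholding, a dose-inference pretext task
    for pre-training with limited clinical labels, block-wise freezing
    transfer learning, and ordinal agreement metrics (mean absolute error,
    exact and close agreement, Spearman rank correlation). The network and
    its optimiser are implemented in the package with RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
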