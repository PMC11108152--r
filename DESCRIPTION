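Package: fmrixcam
Title: Explainable 3D Convolutional Classification of Resting-State fMRI Activity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise resting-state functional activity maps (ALFF,
    fALFF, ReHo via Kendall's coefficient of concordance, and VMHC via Fisher
    z-transformed homotopic correlation) from 4D fMRI volumes, classifies
    Alzheimer's disease versus normal controls with 3D VGG-style convolutional
    networks (fully connected or global-average-pooling heads), and explains the
    trained models with 3D CAM and Grad-CAM heatmaps. Includes a synthetic BOLD
    cohort generator with ROI-localized class effects so that the whole pipeline
    - map formulas, subject-level training protocol, and heatmap localization -
    is testable end to end without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
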