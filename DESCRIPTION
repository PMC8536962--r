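Package: simounet
Title: Single-Input Multi-Output U-Net for Foetal Brain Segmentation in MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the single-input multi-output U-Net (SIMOU-Net), a hybrid
    of the U-Net encoder-decoder and holistically nested edge detection (HED)
    deep-supervision designs, for 2D foetal brain segmentation in MR images.
    The network exposes side outputs along both the contracting and expansive
    paths and combines them into five per-pixel prediction maps that can be
    fused (mean/median/maximum) into within-network ensemble segmentations.
    Includes the hybrid binary cross-entropy plus soft-Dice objective with
    per-head weighting, RMSprop training with early stopping, subject-grouped
    stratified cross-validation, a synthetic foetal-head phantom generator for
    fully self-contained experiments, NIfTI and PNG+JSON volume input/output,
    and the full evaluation suite (Jaccard, Dice, sensitivity, Hausdorff
    distance in mm, brain volume in cm3, mean absolute volume difference,
    and Bland-Altman volume agreement). All network operations (convolution,
    transposed convolution, pooling, batch normalisation and their gradients)
    are provided by compiled kernels within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'simounet-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'architecture.R'
    'io.R'
    'fusion.R'
    'metrics.R'
    'nn_ops.R'
    'forward_backward.R'
    'training.R'
    'pipeline.R'
    'cli.R'
    'phantom.R'
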