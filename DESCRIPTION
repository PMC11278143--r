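Package: carotidseg
Title: Weakly Supervised 2.5D Self-Training Segmentation of Carotid
    Arteries in T1-Weighted MR Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A weakly supervised segmentation pipeline for thin tubular
    structures (carotid arteries) in volumetric T1-weighted magnetic
    resonance images. Axial slices are stacked with their two neighbours
    into 2.5D pseudo-RGB inputs, a residual U-net is trained with a Dice
    loss against per-slice bounding-box weak labels, and a recursive
    self-training scheme refines the labels over several rounds using a
    five-fold ensemble, early-round morphological erosion, a per-carotid
    intersection-over-union acceptance gate, and clipping to the original
    boxes. Includes a synthetic two-tube phantom generator so the full
    pipeline runs end-to-end without external data, NIfTI input and
    output, area-stratified data augmentation, and IoU/Dice reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
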