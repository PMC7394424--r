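Package: ncctangio
Title: Contrast-Free Cerebral Angiography Segmentation from Non-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives cerebral vessel segmentations from paired non-contrast
    CT (NCCT) and CT angiography (CTA) head examinations, and trains a
    convolutional segmentation network to predict those vessels from the
    non-contrast scan alone. Provides DICOM/NIfTI volume handling in
    Hounsfield units, 6-DOF rigid registration by multiresolution mutual
    information, weak vessel-label generation by radiodensity thresholding
    with bone-mask subtraction and connected-component denoising, intensity
    preprocessing by windowing or percentile uniformization, a U-Net-style
    encoder-decoder with self-attention and ICNR-initialized pixel-shuffle
    upsampling trained with the generalized Dice loss under a 1cycle
    learning-rate policy, whole-examination Dice evaluation with k-fold
    cross-validation, and a synthetic head-phantom generator with known
    vessel ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
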