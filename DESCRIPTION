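Package: madgan
Title: Unsupervised Brain MRI Anomaly Detection via Adjacent-Slice
    Reconstruction GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step unsupervised anomaly detection for structural brain
    MRI. Step one trains an image-to-image generative adversarial network
    (a U-Net-like generator with optional self-attention modules against a
    Wasserstein critic with gradient penalty, plus a weighted pixel-sum L1
    reconstruction term) to predict the next three axial slices of a scan
    from the previous three, using healthy scans only. Step two scores
    unseen scans by their average pixel-sum squared reconstruction error
    over all sliding slice triplets (whole-scan or highest-loss
    10-consecutive-set variants) and separates healthy from abnormal scans
    by ROC/AUC. Includes NIfTI/PNG/TIFF volume ingestion onto a fixed
    canvas, a parametric phantom generator with atrophy-like and
    hyperintense-lesion anomaly injectors for fully synthetic end-to-end
    experiments, reconstruction-error heatmap rendering, and a
    reproducible experiment driver. All network primitives (convolution,
    transposed convolution, batch normalisation, self-attention, the
    gradient-penalty double-backward pass, Adam) are implemented in the
    package with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
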