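Package: stressclip
Title: Spatial-Temporal Attention Networks for Facial-Video Stress Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clip-based stress recognition from facial video. Implements the
    full pipeline from raw frame sequences to three-level stress predictions
    (neutral, low, high): face-crop clip construction, facial-landmark image
    preprocessing (min-max normalization and Gaussian blurring), a
    from-scratch ResNet-18 backbone with a spatial attention module, a small
    landmark-image CNN, frame-level temporal attention fusion, and a combined
    cross-entropy plus distance-hinge objective with subject-aware triplet
    sampling. Training and inference run on the CPU through hand-written
    forward and backward passes backed by compiled convolution kernels.
    Includes a seedable synthetic clip generator with planted spatial and
    temporal cues, subject-disjoint k-fold evaluation, clip- and video-level
    metrics, and attention-weight export.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
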