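Package: filamentsim
Title: Simulation and Skeleton-Based Evaluation of Filament Instance
    Segmentation in Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A parametric simulator of interference-reflection-microscopy-like
    images of surface-attached filaments (microtubules) with per-instance
    ground-truth masks, built on a correlated-random-walk geometry model,
    point-spread-function rendering, and a staged stochastic degradation
    operator.  Includes an annotation-free domain tuner that fits generator
    parameters to real reference frames by maximizing embedding cosine
    similarity, normalization of heterogeneous prediction formats (mask
    stacks, labeled maps, anchor-point chains), a skeleton
    intersection-over-union (SKIoU) scoring suite with AP and F1 at SKIoU
    thresholds, downstream biological statistics (counts, lengths, spline
    curvature, KL divergence of their distributions), and a generic few-shot
    hyperparameter-adaptation harness for arbitrary segmenters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
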