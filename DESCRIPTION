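Package: sats
Title: Self-Adaptive Teacher-Student Polyp Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments polyps in unannotated target-domain endoscopy images by
    training per-dataset teacher segmentation networks on multiple annotated
    source-domain datasets, fusing their predictions into reliable pseudo-labels
    with uncertainty- and distribution-distance weighting (UDFusion), and
    training a student network on the fused pseudo-labels. The segmentation
    backbone is a granular attention network (GANet) with a residual
    convolutional encoder, a channel/spatial self-attention identify block and
    foreground/background attention refine blocks, trained with a multi-scale
    Tversky loss. Includes a synthetic multi-domain polyp image generator, the
    seven standard overlap and surface-distance evaluation metrics, and a small
    reverse-mode automatic differentiation engine that the networks train with.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
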