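Package: herbleaf
Title: Herbarium Leaf Morphometrics and Species Classification
Version: 0.1.0
Authors@R: person("herbleaf", "maintainers", email = "herbleaf@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for species-level classification of
    pressed herbarium leaves: scribble-seeded graph-cut segmentation, an
    oriented multi-scale line operator producing per-pixel vein strength and
    orientation maps, geodesic tracing and cubic straightening of the main
    vein, extraction of Fourier contour descriptors, classical shape
    descriptors and strength-weighted vein-orientation histograms, and linear
    one-against-one support vector classification with leave-one-out
    evaluation. Includes a parametric synthetic-leaf generator with ground
    truth for benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
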