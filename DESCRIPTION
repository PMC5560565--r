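Package: octseg
Title: Graph-Based Multi-Surface Segmentation of Mouse Retinal OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the automated segmentation of murine spectral-domain
    optical coherence tomography (SD-OCT) volumes and the downstream analysis
    of retinal layer thickness. Retinal surfaces are recovered simultaneously
    as the exact global optimum of a constrained multi-surface energy via a
    single minimum s-t cut, with boundary likelihoods supplied either by
    image gradients or by random-forest voxel classifiers trained on sparse
    manual delineations. Includes a three-stage segmentation pipeline for
    healthy (10 surfaces) and light-damage (6 surfaces) retinas, a synthetic
    layered-phantom generator with ground truth and simulated raters,
    validation metrics (unsigned border position error, intra- and
    inter-rater variability tables), and eight-layer quadrant thickness
    statistics with paired group comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
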