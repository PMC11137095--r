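Package: hemsi
Title: Annotation-Free MSI Status Assessment from H&E Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing microsatellite instability (MSI) status of
    endometrial carcinoma directly from H&E-stained whole-slide images without
    pixel-level annotations. Implements foreground patch selection by optical-
    density color deconvolution of the eosin channel with dual thresholding and
    marker-ink exclusion, tumor-attention scoring of high-resolution patches
    through a pluggable per-pixel segmenter backend, iterative spaced patch
    sampling of representative tumor-like patches, and a weighted-softmax
    integrated decision model that aggregates per-patch classifier
    probabilities into a slide-level MSI call. Includes a seeded synthetic
    slide generator with planted ground truth (tissue, tumor, pen markers,
    labels) and mock segmenter/classifier backends so the whole pipeline is
    testable without external slides or trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
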