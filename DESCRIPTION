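Package: sweeplens
Title: Parameter-Space Sweeps and Table-Lens Exploration for Image
    Analysis Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cartesian parameter sweeps over image-analysis plugins,
    persisted as self-describing manifests of data records (parameter
    combination + output measures + output images), together with a
    deterministic table-lens interaction algebra (nested multi-column
    sorting, correlation-driven smart sorting, context-sensitive run
    selection, interval filtering, domain-coverage strips) and static
    renderers for the tabular view and blended image grids. Ships a
    colour-deconvolution backend for H&E histology with corrective
    stain-vector parameters and negative-coefficient quality measures,
    a thresholding nuclei-detection fixture, and synthetic-data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    igraph,
    EBImage,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
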