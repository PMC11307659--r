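Package: vasoprofile
Title: Morphological Profiling of Endothelial Monolayers from High-Content Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based morphological-profiling pipeline for confluent
    endothelial monolayers imaged in four channels (nuclei, adherens
    junctions, F-actin, mitochondria). Provides a seeded synthetic image
    generator with ground-truth masks, per-image quality control and
    retrospective illumination correction, nuclei segmentation by local
    thresholding and watershed, cell delineation by nuclei-seeded
    image-weighted Voronoi propagation, extraction of more than 800
    single-cell features (shape, moments, intensity, texture, radial
    distribution, colocalization), plate-wise z-score normalization,
    factor-analysis fingerprinting, and supervised stratification by
    linear discriminant analysis and partial least squares with repeated
    hold-out cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    MASS,
    mixOmics,
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
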