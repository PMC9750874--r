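Package: imdassay
Title: Spatial Single-Cell Analysis of Intratumor Microdevice Drug Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of chromogenic multiplex immunohistochemistry data
    collected around drug-releasing implantable microdevice reservoirs.
    Provides stain separation (hematoxylin deconvolution and AEC extraction
    via the CMYK yellow channel), watershed nuclear segmentation and
    single-cell feature extraction, hierarchical threshold/polygon gating
    into standard tumor-microenvironment cell types, distance-based spatial
    clustering, distance-from-well abundance profiles, pairwise proximity
    statistics, and paired assay-versus-control enrichment tests, together
    with a ground-truthed synthetic scene and image generator for
    calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    mclust
Config/testthat/edition: 3
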