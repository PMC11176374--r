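Package: rpemosaic
Title: Morphometry of Retinal Pigment Epithelium Mosaics in Adaptive
    Optics Retinal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of the retinal pigment epithelium (RPE)
    cell mosaic in adaptive-optics trans-scleral flood-illumination (AO-TFI)
    retinal images. Provides tile-based image quality scoring and masking,
    cell-center detection with bounded Voronoi tessellation and mosaic
    morphometrics (area, perimeter, equivalent diameter, neighbor counts,
    density), locally adaptive segmentation of intracellular hypo-reflective
    regions with shape descriptors (solidity, circularity), landmark-based
    similarity registration onto infrared fundus frames with physical pixel
    scaling, multimodal grading bookkeeping, per-eye aggregation with
    baseline matching, and Welch-corrected group comparisons. A seeded
    synthetic mosaic generator with full ground truth makes every stage of
    the pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
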