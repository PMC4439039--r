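Package: clearbrain
Title: Quantitative Analysis of Cleared Whole-Brain Light-Sheet Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of cleared mouse brains imaged
    by light-sheet fluorescence microscopy: mosaic stitching of tiled z-stacks,
    binary tissue masking from a background-window histogram threshold,
    depth-dependent Beer-Lambert attenuation correction with automated
    estimation of the per-axis absorption coefficients, aggregation of 3D
    cell-body annotations into brain-region connectivity tables with derived
    input fractions, longitudinal affine re-alignment with scale-change and
    display-range reporting, and plate-assay quantification of fluorescent
    protein preservation. A synthetic-data module generates phantom brain
    volumes, tile mosaics, shadow-stripe illumination simulations and
    replicate-structured plate assays with known ground truth, so every
    pipeline stage is testable without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
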