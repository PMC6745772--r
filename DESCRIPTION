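Package: aortadense
Title: Regional Aortic Wall Strain Mapping from Cine DENSE CMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Post-processing pipeline for 2D cine DENSE (Displacement ENcoding
    with Stimulated Echoes) cardiovascular magnetic resonance of the aortic
    wall. Decodes wrapped displacement-encoded phase images into per-voxel
    displacements, tracks wall voxels through the cardiac cycle, computes
    circumferential Green-Lagrange strain over 16 sectors by a bilinear
    quadrilateral finite-element scheme, and derives normalized circumferential
    strain (NCS), the strain heterogeneity index, the mean displacement angle,
    and observer-agreement (reproducibility) metrics. Includes a synthetic
    DENSE generator for an analytically deforming annulus with exact ground
    truth, so every stage of the pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
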