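Package: optquant
Title: Quantification of EdU Proliferation in Optical Projection Tomography
    Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cell proliferation in 3-D reconstructed
    optical projection tomography (OPT) volumes of the adult zebrafish brain.
    Implements three complementary analyses of EdU-labelled whole-brain
    stacks: an anterior-posterior intensity profile built from horizontal
    maximum projections (histogram analysis), full-depth region-of-interest
    voxel volumetry using a 16-bin intensity quantizer with black-bin
    exclusion (structure analysis), and every-Nth-slice sampling of
    neurogenic-niche masks (slice analysis). Also provides autofluorescence
    brain-volume morphometry by thresholded segmentation, one-way ANOVA with
    Tukey post-hoc group statistics, a synthetic OPT brain phantom generator
    with ground truth for end-to-end validation, and small bench-protocol
    calculators for the EdU staining solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
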