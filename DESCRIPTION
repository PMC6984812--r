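Package: laminar
Title: Cortical-Depth-Resolved fMRI Analysis with a Synthetic Cortical Patch Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing laminar (cortical-depth-resolved) fMRI of
    multisensory and attentional effects: looming-stimulus and block-design
    construction with behavioural scoring, a ground-truthed synthetic
    generator of vertex-by-depth parameter-estimate datasets and voxel time
    series, a mixed block-event first-level GLM with AR(1) generalized least
    squares and discrete-cosine drift, equivolume depth grids and laminar
    profile contrasts with a constant-plus-linear shape GLM, step-down group
    inference for 2 (shape) x 2 (ROI) designs, per-depth linear-SVM decoding
    with leave-one-run-out cross-validation and exact sign-permutation
    pattern-similarity tests, and cross-validated vertex-sorting raster
    regression linking the laminar shape of one contrast to another.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    lme4,
    lmerTest,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
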