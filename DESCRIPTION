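Package: roiscope
Title: Semi-Automated Analysis of Functional Fluorescence Imaging of Neural Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the semi-automated analysis of dynamic fluorescence
    imaging experiments on neural circuits, such as multi-photon calcium
    imaging of synaptic terminals. Regions of interest of widely varying
    brightness are detected by thresholding the Laplace operator of a source
    image, per-ROI time series are extracted, background-corrected and
    normalised to dF/F with a histogram-mode baseline robust to spontaneous
    activity, responses are grouped by single-linkage clustering of pairwise
    trace distances, and each unit is assigned a relative depth within a
    layered structure (for example the retinal inner plexiform layer) via
    isocontours interpolated between two user-drawn borders. Includes a
    synthetic-data generator with planted ground truth, a flat-file results
    store, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    igraph,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
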