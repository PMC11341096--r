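Package: fpmtools
Title: Object-Based Analysis of Fluorescence Polarization Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for excitation-resolved fluorescence polarization microscopy
    (FPM). Computes pixelwise orientational order and azimuth maps from
    four-polarization image stacks, segments punctate and filamentous
    structures, extracts per-object morphological, intensity and polarization
    features, derives object midlines from Voronoi diagrams of object
    boundaries to express azimuths relative to structure orientation, and
    provides axial circular statistics, object filtering/labeling/clustering,
    composite visualizations, and a synthetic-scene generator with per-pixel
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    deldir,
    igraph,
    mgcv,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
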