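Package: afmtexture
Title: Surface-Texture Classification and Probability Heatmaps for AFM Images of Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-channel atomic-force-microscopy (AFM) maps of cell
    surfaces into areal surface-texture parameter vectors (ISO-25178 style
    amplitude, hybrid, spatial, functional and volume families), ranks the
    parameters by Gini importance, trains a Gaussian-process probability
    classifier (RBF kernel, Laplace approximation) separating cells of low and
    high cancer aggressiveness, locates the informative feature scale with a
    moving-average blur scan, and rasters the trained classifier over
    overlapping sliding windows to produce per-pixel class-probability
    heatmaps that localize the surface regions driving the classification.
    Includes a seed-deterministic synthetic generator of two-class,
    multi-channel AFM-like textures for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    randomForest,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
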