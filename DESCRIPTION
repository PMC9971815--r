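Package: myospark
Title: Calcium Spark and Transient Dyssynchrony Mapping for Cardiomyocyte Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel 2D time-lapse recordings of
    ventricular cardiomyocytes acquired with high-speed light-sheet (or other
    widefield) fluorescence microscopy. Co-registers the calcium-indicator and
    membrane-stain channels, segments the cell footprint, extracts the
    transverse-tubule network and nuclei, and maps the Euclidean distance to
    the nearest tubule (DNT). Detects spontaneous calcium sparks in the
    unpaced part of a recording with a two-pass, per-pixel hysteresis
    thresholding algorithm and characterizes their morphology (amplitude,
    FWHM, FDHM, spark mass). Maps the stimulus-referenced time-to-half-maximum
    (T50) of paced calcium transients pixel by pixel, summarizes regional
    dyssynchrony, and correlates spark placement and T50 with tubule
    proximity. Includes the distribution-routing statistical comparison scheme
    used for group analyses and a seeded synthetic phantom generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
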