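Package: padquant
Title: Quantitation of Colorimetric Paper-Based Analytical Devices from RGB Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying colorimetric assays on microfluidic
    paper-based analytical devices (uPADs) read with flatbed scanners or
    cameras. Extracts per-zone mean RGB intensities from scanned images of
    circular detection zones (or from tabular ImageJ exports), computes a
    panel of nineteen RGB-based analytical-signal transforms (single
    channels, channel means, blank-referenced log ratios and differences,
    channel-sum ratios, the Euclidean RGB distance, and a log colour-product
    transform) plus HSV channels, fits linear calibrations with figures of
    merit (sensitivity, sensitivity error, limit of detection, confidence
    limits of the fitted response), computes a delta-signal-ratio statistic
    measuring the ability to discriminate nearby concentrations, and ranks
    the transforms to recommend a data-treatment method for a given assay.
    Includes a synthetic scan generator with known ground truth and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    jpeg,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
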