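Package: polascore
Title: Depth-Calibrated Scoring of Mirror-Symmetric Cell Polarity from
    Two-Cell Fluorescence Ratios
Version: 0.1.0
Authors@R:
    person("polascore", "developers", email = "polascore@example.org",
           role = c("aut", "cre"))
Description: Quantitative scoring of asymmetric cell division from paired
    nuclear fluorescence intensities. A symmetric control reporter is used
    to fit a linear depth-attenuation calibration of log intensity ratios
    against inter-nucleus focal-plane distance; a Student-t confidence band
    around the calibration classifies each reporter measurement as normal,
    reversed, or symmetric (signed) and polarized or unpolarized (absolute).
    Includes penetrance statistics (integer-count reconstruction from
    rounded percentages, Pearson chi-square enhancement tests, pooled-
    variance Student t-tests), a seeded synthetic-data generator for
    end-to-end validation, and violin-plot summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
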