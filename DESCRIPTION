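Package: lightdose
Title: Metrics and Preprocessing for Wearable Light-Logger Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Device-agnostic analysis of personal light-exposure time series
    recorded by wearable light loggers and dosimeters. Reads epoch-level,
    multi-channel CSV exports through a configurable dialect, supports
    masking of non-wear periods, truncation, resampling, zero-phase
    Butterworth filtering, log transformation, thresholding and
    binarization, and computes the standard exposure metrics of
    chronobiology: summary statistics, thresholded exposure level, time
    above threshold (TAT), mean light timing above threshold (MLiT),
    L5/M10 nonparametric windows, interdaily stability (IS) and intradaily
    variability (IV). Includes a seeded synthetic-recording generator and a
    command-line interface for single-subject and batch workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
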