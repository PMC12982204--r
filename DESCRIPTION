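Package: scarfkit
Title: AOI Sequence Analysis and Scarf Plots for Eye-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for analysing areas-of-interest (AOI) sequence
    exports from eye trackers. Parses delimited gaze-event files with
    structure-based format detection and bounded-memory streaming, builds a
    canonical in-memory gaze dataset with non-destructive AOI merging,
    recolouring and participant grouping, computes AOI metrics (time to
    first fixation, fixation count, average fixation duration, dwell time)
    with an independent rasterization oracle and multi-interval
    reconstruction, constructs resolution-independent scarf-plot geometry
    under absolute, relative and ordinal timelines with overlap splitting
    and dynamic-AOI visibility bands, counts AOI-to-AOI transitions, and
    exports publication figures, metrics and event tables,
    ScanGraph-compatible scanpath sequences and reproducible session files.
    A deterministic synthetic-recording generator makes every component
    testable without real eye-tracker exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
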