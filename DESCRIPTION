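Package: meaburst
Title: Single-Electrode Burst Metrics for Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-electrode burst activity in
    multi-electrode array (MEA) recordings downstream of AxIS Navigator
    (Axion BioSystems) processing. Reads electrode burst list CSV exports,
    detects bursts from spike timestamps with an inter-spike-interval
    threshold rule, summarises the four standard burst parameters (number
    of bursts, mean burst duration, mean spikes per burst, and mean
    within-burst inter-spike interval) over labelled time windows at both
    single-electrode and whole-well level, quantifies electrode consistency
    with the average-raters intraclass correlation ICC(2,k), simulates
    bursty spike trains with known ground truth for testing, and draws
    grouped bar charts laid out on the physical electrode grid.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
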