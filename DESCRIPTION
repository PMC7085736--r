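Package: depthbreathe
Title: Non-Contact Breathing Analysis and Sleep Apnea Detection from Depth Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts a breathing signal from depth-camera frame sequences by
    region-of-interest frame differencing, band-pass filters and resamples it
    to a uniform 10 Hz rate, computes per-window spectral features (dominant
    breathing frequency and standard deviation), labels apnea versus normal
    breathing with an unsupervised two-neuron competitive neural network
    (with a K-means baseline), and evaluates classifications at per-sample
    and per-event level with confusion-matrix metrics and events-per-hour
    reports. Includes a synthetic depth-recording generator with configurable
    breathing rate, apnea event schedules, sensor noise and frame-rate jitter,
    so the whole workflow is testable without recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
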