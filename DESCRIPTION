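Package: rppgbench
Title: Remote Photoplethysmography Vital Signs and Skin-Tone Agreement Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts blood-volume-pulse signals from facial-video RGB traces with
    the plane-orthogonal-to-skin (POS) chrominance projection and a convolutional
    heartbeat-template filter, estimates heart rate, spectral signal quality and
    time- and frequency-domain heart rate variability, and benchmarks the estimates
    against contact-sensor ground truth with agreement statistics (MAE, mean error,
    Bland-Altman limits, best-fit lines) stratified by signal quality, Fitzpatrick
    skin-tone band and gender. A synthetic cohort generator with known ground truth
    (RR series, contact-PPG waveforms, skin-tone-dependent RGB traces and toy frame
    stacks) makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
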