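Package: qaradar
Title: Quantified Activity Assessment from Impulse-Radar Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-sensor impulse-radio ultra-wideband (IR-UWB) radar
    recordings of moving subjects, converts raw range-bin frames into per-minute
    activity scores (adaptive clutter removal, Hilbert-envelope movement
    detection, threshold calibration from empty-room recordings, median fusion
    across sensors), and compares group activity curves with functional ANOVA:
    globalized pointwise F-tests and F-max tests with permutation null
    distributions, velocity-curve tests, pointwise distribution summaries, rank
    correlations and scalar group comparisons. Includes a synthetic cohort
    generator emulating a stable control group and a group whose movement
    intensity rises with inflated dispersion after a changepoint, plus a simple
    raw-binary recording container and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
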