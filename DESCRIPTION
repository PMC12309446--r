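Package: eegqc
Title: Quality Control for Field EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated data-quality assessment for multichannel resting-state
    EEG collected outside the lab. Implements FASTER-style Z-score criteria
    (pairwise correlation, variance, Hurst exponent, powerline band power) and
    robust-statistics PREP-style criteria (flat/NaN screening, robust amplitude,
    windowed correlation, high/low-frequency noisiness) for bad-channel
    detection, plus epoch-level variants of both, Welch spectra and peak alpha
    frequency, bootstrap group comparisons, a daily field-team quality
    dashboard, and a seeded synthetic-EEG generator with ground-truth artifact
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
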