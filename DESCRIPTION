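Package: thermosense
Title: Thermal Sensation Modelling from Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating thermal sensation (TS) prediction
    models from wearable physiological signals. Simulates seeded climate-chamber
    cohorts (ECG RR series, EMG, EEG, GSR, skin temperatures under a 2x2x2
    temperature/humidity/fan factorial), extracts the standard 22-feature set
    (HRV time and frequency domain, EMG amplitude descriptors, EEG band
    amplitudes and relative powers, tonic GSR, body and environment means),
    selects predictive feature subsets with a two-stage greedy wrapper
    (feature increment then redundant-feature removal) over interchangeable
    regression backends, and benchmarks the fitted model against a from-scratch
    Fanger predicted mean vote (PMV) heat-balance baseline with correlation,
    resampled train/test, gender-error and signal-importance reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    signal,
    kernlab,
    e1071,
    rpart,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
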