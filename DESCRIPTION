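Package: bssrp
Title: Bowel-Sound Stimulus-Response Plots from Abdominal Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bowel-sound (BS) segments and episodes in abdominal
    audio recordings with a cepstral-feature (PNCC + LPCC) neural-network
    classifier, extracts the four classical BS time-domain acoustic
    features (episodes per minute, sound-to-sound interval, power, length)
    over pre- and post-ingestion analysis intervals, and builds BS-based
    stimulus-response plots (BSSRPs) together with their exponential and
    log-log linear fits, Pearson correlation tests, a log-log plot
    distance metric, and detection-limit diagnostics.  Includes a
    synthetic-recording and synthetic-cohort generator so the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
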