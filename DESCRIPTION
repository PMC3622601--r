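Package: songtrack
Title: Passive Acoustic Localization and Movement Analysis of Singing Whales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking singing whales with bottom-mounted hydrophone
    arrays. Simulates time-synchronized multichannel recordings of a moving
    acoustic source (correlated-random-walk movement, propagation delay,
    spreading loss, band-limited ambient noise, per-sensor clock drift),
    detects song by normalized spectrogram cross-correlation against a
    template, localizes selected song units in the horizontal plane by
    correlation-sum grid search over candidate positions, assembles
    quality-controlled locations into per-session tracks with moving-average
    smoothing, and computes step- and track-level movement statistics
    (distance, duration, speed, net displacement, straightness index),
    including seasonal comparisons and two-singer interaction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
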