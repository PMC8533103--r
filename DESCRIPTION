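Package: cardiowave
Title: Automated Cardiac Rhythm Measurement from Heart Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Video-based photoplethysmography for small transparent animals
    (zebrafish larvae, Daphnia). Reduces rectangular atrium and ventricle
    regions of interest in a heart video to per-frame mean grayscale
    intensity series, conditions the signals (smoothing spline, zero-phase
    Butterworth bandpass), detects beats by prominence-filtered extrema, and
    reports heart rate in beats per minute, chamber interval endpoints
    (A-A, V-V, A-V, V-A), Poincare sd1/sd2 regularity, and the lagged
    normalized cross-correlation between chambers. Includes a ground-truthed
    synthetic beating-heart video generator and a lossless uncompressed AVI
    reader/writer so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
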