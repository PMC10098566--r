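Package: rppg
Title: Contactless Heart-Rate Estimation from Video by Chrominance-Based
    Remote Photoplethysmography
Version: 0.1.0
Authors@R:
    person("rppg", "maintainers", email = "rppg@example.org", role = c("aut", "cre"))
Description: A tested pipeline for camera-based (contactless) heart-rate
    measurement. Video frames are reduced to a forehead region of interest
    via an 81-point facial landmark schema, per-frame mean RGB traces are
    conditioned (linear detrend, max-abs normalization, moving-average
    smoothing, 0.7-4 Hz third-order Butterworth band-pass), projected onto
    chrominance axes (X = 3R - 2G, Y = 1.5R + G - 1.5B, pulse = X - mu*Y
    with mu the ratio of standard deviations), and read out spectrally:
    the dominant in-band FFT peak frequency times 60 is the heart rate in
    beats per minute. Includes an optional low-light double-plateau
    histogram equalization stage tuned by a cuckoo-search optimizer, a
    synthetic pulsatile-video generator with known ground truth for
    end-to-end verification without human subjects, and an evaluator
    implementing the |error| < 3 bpm accuracy criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
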