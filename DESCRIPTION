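Package: rehabrecog
Title: Activity Recognition for Shoulder Rehabilitation Exercises from
    Wearable Inertial Sensor Streams
Version: 1.0.0
Authors@R:
    person("Rehabrecog", "Developers", email = "rehabrecog@example.org",
           role = c("aut", "cre"))
Description: Recognizes six frozen-shoulder rehabilitation exercises from
    wrist-worn inertial sensor streams. Parses and validates wireless
    sensor-network packet logs, converts analog-to-digital count blocks to
    physical acceleration and angular velocity, derives the included-angle
    feature between consecutive acceleration vectors, assembles overlapping
    25-second window entries, and trains a from-scratch 800-5-6
    back-propagation neural network with validation-based early stopping.
    Also provides the characteristic-space cluster-overlap test, a spectral
    pipeline (FFT spectrum, peak grouping, FIR low-pass with downsampling,
    spectrum enveloping and magnitude-difference filter-parameter
    selection), and a seeded synthetic exercise-signal simulator that
    stands in for the wearable hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
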