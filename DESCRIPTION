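Package: myocomp
Title: Myoelectric Intention Estimation and Compensatory-Movement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for pattern-recognition
    myoelectric prosthesis control and for quantifying the compensatory
    trunk movement it induces. Provides a seeded multi-channel surface-EMG
    simulator with class-dependent band-power signatures, an FFT band-power
    feature extractor (Hann-windowed frames, eight 50-Hz bands per channel),
    a feed-forward intention classifier with a recognition-stabilization
    filter and wrist-excluding hand-command mapping, trunk-angle and
    distortion-level kinematics from pose-landmark streams, elbow-trajectory
    summaries, and condition-comparison statistics (trial filtering,
    histograms with normal overlays, t tests, 30-second block throughput).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    nnet,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
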