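Package: mocapclean
Title: Detection, Classification and Repair of Artifact Distortions in
    Optical Motion-Capture Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Marker-wise detection and classification of four artifact
    classes in optical motion-capture trajectories (isolated peaks, heavy
    noise bursts, rectangular step changes, slow deviations), using
    derivative analysis, Savitzky-Golay filtering, one-dimensional
    mathematical morphology and a loose neighbour-based neural predictor
    driven by a functional body mesh.  Includes a synthetic quasi-static
    sequence generator, a controlled artifact contamination simulator with
    ground-truth logging, interval-targeted trajectory repair, and
    evaluation harnesses (confusion matrices, per-class rates, RMSE,
    moving-statistics baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
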