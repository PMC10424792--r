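Package: bcgsleep
Title: Heart-Rate Estimation During Sleep from Ballistocardiogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A low-cost telemedicine pipeline for estimating heart rate during
    sleep from ballistocardiogram (BCG) signals recorded by a pressure-sensor
    belt, validated against a photoplethysmography (PPG) pulse-oximeter
    reference. Provides packet framing and reassembly with loss accounting,
    saturation/outlier repair, 2-10 Hz Butterworth band-pass filtering,
    8-second windowing and normalization, an algorithmic J-peak detector based
    on signal cubing and weighted IJK triplet scoring, a compact 11-layer
    strided 1-D convolutional network regressing window heart rate, PPG
    peak-based reference heart rates, patient-wise MAE/MAPE evaluation, and a
    seeded synthetic overnight-session simulator with ground-truth beat
    annotations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
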