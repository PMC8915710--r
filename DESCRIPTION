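Package: ppgvalsalva
Title: Estimating Intravascular Volume Status from Pulse-Oximeter Waveforms
    During a Valsalva Maneuver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing intravascular
    volume status in cirrhosis from finger photoplethysmography (PPG)
    waveforms recorded around a standardized Valsalva maneuver. Provides a
    synthetic cohort generator in which the end-strain attenuation of pulse
    amplitude encodes cardiac filling pressure, beat detection and per-beat
    feature extraction (amplitude, half-height width, area under the curve,
    window RMS power), capped greedy forward feature selection, fivefold
    cross-validated regression of filling pressure, classification of volume
    overload with linear discriminant analysis and four comparator
    classifiers against majority-class dummy and BNP-only baselines, and
    Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    rpart,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
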