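Package: ecgdys
Title: Personalized Dysglycemia Screening from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A personalized pipeline that screens for dysglycemia (blood glucose
    above 200 mg/dL or below 70 mg/dL) from single-lead ambulatory ECG. The
    pipeline segments 125 Hz lead-II signal into fixed one-second beats anchored
    on the R peak, delineates the P-Q-R-S-T fiducial points by stationary-wavelet
    analysis, extracts 26 morphology features (intervals, amplitude differences,
    slope gradients, and the R-R interval), and trains a per-subject linear
    nu one-class support vector machine on euglycemic beats only, flagging
    dysglycemia per beat and per 10-second majority-vote window. A calibrated
    synthetic ECG and blood-glucose generator with glycemic-state-modulated beat
    morphology makes every stage testable without access to clinical waveform
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
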