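Package: betaburst
Title: Sensorimotor Beta Events and Corticospinal Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and characterization of transient sensorimotor beta
    (15-30 Hz) events in pre-stimulus EEG and trial-by-trial prediction of
    TMS-evoked motor-evoked potential (MEP) amplitudes from event morphology.
    Provides a ground-truth-annotated synthetic EEG/EMG generator, Hjorth
    spatial filtering and artifact rejection, multitaper spectral estimation
    of the individual beta frequency, Morlet wavelet beta-power time series,
    percentile-threshold burst detection with half-maximum duration and
    edge-event rules, MEP extraction with voluntary-contraction filters, and
    linear mixed-effects modeling with likelihood-ratio comparisons and
    per-subject k-fold cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
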