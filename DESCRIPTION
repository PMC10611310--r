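Package: wristvalid
Title: Validation of Wrist-Worn Heart Rate Variability and Electrodermal
    Activity Measurements Against Gold-Standard Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how well a wrist-worn photoplethysmography and
    skin-conductance device reproduces gold-standard heart rate variability
    (HRV) and electrodermal activity (EDA) metrics. Implements
    accelerometer-informed reconstruction of inter-beat intervals from the
    blood volume pulse (subject-specific band-pass selected by power spectral
    density subtraction, diastolic foot-point detection, distribution-based
    artifact correction), ECG R-peak detection (Pan-Tompkins), Lomb-Scargle
    HRV spectra, convex tonic/phasic EDA decomposition with stationary Haar
    wavelet artifact rejection, and the full device-agreement statistics
    suite (detection and artifact rates, Spearman ranking bands,
    Bland-Altman limits of agreement with bias significance, Friedman tests
    with post hoc comparisons). A synthetic paired-recording generator with
    known ground truth drives end-to-end testing without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
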