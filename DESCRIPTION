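Package: eegtf
Title: Morlet Wavelet Time-Frequency Analysis for Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Time-frequency decomposition of event-locked, epoched EEG with
    complex Morlet wavelets. Builds wavelet banks with selectable
    normalization, computes per-trial continuous wavelet transforms and
    averages them as total-induced or evoked amplitude, power or complex
    coefficients, handles convolution edge distortion by padding and
    chopping, applies subtractive, subtractive-normalized or divisive
    baseline correction and dB conversion, reads EEGLAB epoched datasets,
    writes ERPWAVELAB-compatible MAT containers, exports window-averaged
    values for third-party statistics, renders time-frequency plots and 2D
    scalp maps, and simulates epoched EEG with controllable oscillatory
    bursts for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    mgcv,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
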