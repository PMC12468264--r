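Package: mvmdnet
Title: Multivariate Variational Mode Decomposition and Spatio-Temporal
    Neural Classification of Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint decomposition of multichannel electrophysiological
    signals into frequency-aligned intrinsic mode functions by
    multivariate variational mode decomposition (MVMD), solved with the
    alternate direction method of multipliers in the frequency domain.
    Includes EEG preprocessing (notch and band-pass filtering, epoching,
    overlap augmentation, channel selection), short-time Fourier
    spectrogram features per mode, a convolutional / bidirectional
    gated-recurrent / Transformer-encoder classifier with training and
    cross-validation protocols (epoch-level stratified and
    patient-level subject-independent), synthetic multichannel signal
    generators for download-free testing, and readers for two-column
    ASCII signal pairs and EDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
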