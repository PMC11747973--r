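Package: trfscape
Title: Temporal Response Function Modelling of Naturalistic Soundscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward (encoding) modelling of EEG responses to naturalistic
    soundscapes with lagged ridge regression. Extracts acoustic features
    (energy-novelty onsets, Hilbert and power envelopes, mel-spectrogram),
    sound-identity and condition markers, fits temporal response functions
    with segment-wise cross-validated regularization, and compares feature
    sets via nested model evaluation, variance partitioning with
    nonnegativity bias correction, cross-prediction with latency-shift
    correction, and explainable-sample (masked) scoring. Includes a
    synthetic-data generator (tone soundscapes, triphasic P1-N1-P2 kernels,
    1/f pink noise at controlled SNR) so every stage is testable without
    external recordings, plus an ERP-in-pink-noise SNR sweep simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
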