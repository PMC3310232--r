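Package: sgphrv
Title: Smoothing by Gaussian-Process Priors for Heart Rate Variability Tachograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zero-phase, time-varying second-order smoothing of irregularly
    sampled heart-rate-variability tachograms without resampling. Builds the
    nonuniform second-difference penalty operator, solves the regularized
    smoothing problem by sparse Cholesky factorization, calibrates the
    regularization weight to a -3 dB cut-off frequency in closed form via the
    bilinear transform, chains two smoothing passes into a band-pass
    (detrend then low-pass), and analyses the filtered irregular series
    directly with the Lomb-Scargle periodogram, including the standard
    VLF/LF/HF heart-rate-variability band powers. Includes a synthetic
    tachogram generator (band-limited Gaussian RR noise on an irregular time
    axis) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    signal,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
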