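Package: wannpm
Title: Wavelet Artificial Neural Networks for Daily PM2.5 Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Next-day forecasting of daily PM2.5 concentration from
    meteorological covariates and lagged PM2.5 with one-hidden-layer
    feed-forward neural networks and their wavelet hybrids (WANN).  Provides
    multiresolution discrete wavelet decomposition (Mallat pyramid) with a
    21-wavelet registry and mother-wavelet selection by inter-component
    correlation, a 12-algorithm trainer registry including
    Levenberg-Marquardt and Bayesian regularization, chronological staged
    splits with min-max normalization, correlation-based input ranking,
    grid search and k-fold cross-validation, staged MAE/RMSE/R evaluation
    reports, a seasonal autoregressive synthetic-data generator, and a
    command-line interface for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
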