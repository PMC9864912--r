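# wannpm

Wavelet artificial neural networks (WANN) for next-day forecasting of daily
PM2.5 concentration from meteorological covariates and lagged PM2.5.

Daily mean PM2.5 (μg/m³) is a noisy, seasonal, strongly autocorrelated
series coupled to weather: colder, high-pressure days accumulate more fine
particulate matter. `wannpm` implements the full modelling protocol for
forecasting tomorrow's concentration from today's observations, for air
quality researchers and exposure modellers who want a transparent,
fully-reproducible reference implementation:

- **Lagged supervision.** Predictors are the fourteen meteorological
  elements at day *t* plus PM2.5(*t*), PM2.5(*t*−1), PM2.5(*t*−2); the
  target is PM2.5(*t*+1). Rows are split chronologically into training
  (80%), verification (10%) and predicting (10%) stages, and min–max
  normalized, `S = (s − s_min)/(s_max − s_min)`.
- **Wavelet expansion.** Each input series can be decomposed by a 2-level
  discrete wavelet transform (Mallat pyramid) into full-length components
  CA2 + CD2 + CD1 that sum exactly back to the signal. A WANN feeds all
  three components of every input to the network (17 inputs → 51). The
  mother wavelet is chosen from a 21-wavelet registry (db2–db6, sym2–sym6,
  coif1–coif5, six spline biorthogonal wavelets) by minimizing the mean
  absolute correlation between components; for bior1.1 (Haar) under
  periodization the components are exactly uncorrelated.
- **One-hidden-layer network.** `Q = f₂(W₂ f₁(W₁x + b₁) + b₂)` with
  activations among logsig, tansig, purelin, poslin, trained full-batch
  against the global error `E = (1/l) Σ (Tⱼ − Qⱼ)²` by any of twelve
  algorithms: `gd gdm gdx rp scg cgf cgp cgb bfg oss lm br` — including
  Levenberg–Marquardt (`lm`) and Bayesian regularization (`br`, evidence
  framework: minimizes `β·E_D + α·E_W` with α, β re-estimated from
  `γ = N − 2α·tr(H⁻¹)`).
- **Selection & evaluation.** Correlation-based input ranking, grid search
  over hidden sizes (1–21), trainers and activation pairs, contiguous-block
  k-fold cross-validation, and staged MAE / RMSE / R reports.
- **Synthetic data.** A seasonal AR(1) generator with known ground truth
  (negative temperature coupling, positive pressure coupling, optional
  short-period component) so the whole pipeline is testable without any
  download.

## Worked example

```r
library(wannpm)

gen    <- generate_daily_series(synthetic_config(n_days = 730, multiscale = TRUE, seed = 42))
series <- gen$series

# 1. pick the mother wavelet whose components are least correlated
select_mother_wavelet(series$pm25)$best
#> [1] "bior1.1"

# 2. build the lagged design and the chronological stages
sm    <- build_supervised(series, pm_lags = c(0, 1, 2), met_vars = met_schema())
split <- chronological_split(sm)
#> stage_split: training 581 / verification 73 / predicting 73 rows

head(rank_inputs_by_correlation(sm), 3)
#>   variable          r     abs_r       p_value significant_0.01
#> 1   pm25_t  0.8765325 0.8765325 2.032868e-232             TRUE
#> 2      mat -0.8393812 0.8393812 3.908969e-194             TRUE
#> 3    maxat -0.8374174 0.8374174 2.178333e-192             TRUE

# 3. fit the matched plain and wavelet networks and compare held-out stages
cfg  <- train_config("lm", max_epochs = 60, seed = 42)
ann  <- fit_forecaster(sm, split, preset_model_spec("ANN1",  config = cfg))
wann <- fit_forecaster(sm, split, preset_model_spec("WANN1", config = cfg))
tab  <- performance_table(list(ann, wann), sm, split)
tab[tab$stage == "predicting", c("model", "stage", "MAE", "RMSE", "R")]
#>   model      stage   MAE  RMSE      R
#> 3  ANN1 predicting 6.073 7.342 0.7806
#> 6 WANN1 predicting 4.051 5.342 0.8896
```

PM2.5(*t*) dominates the input ranking, the temperature block correlates
negatively, and on data with genuine multiscale structure the WANN beats the
matched ANN on the untouched predicting stage (RMSE 5.3 vs 7.3 μg/m³ here) —
the wavelet components separate the slow seasonal level from the short-period
oscillation that a raw lagged input blurs together.

A command-line interface wrapping the same functions ships at
`inst/cli/wannpm.R` (subcommands `simulate`, `decompose`, `select-wavelet`,
`compare-periods`, `train`, `run`, `cv`, `grid-search`, `evaluate`).

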