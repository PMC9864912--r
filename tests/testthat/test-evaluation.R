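test_that("metrics follow their definitions on hand-computed cases", {
  m0 <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$MAE, 0)
  expect_equal(m0$RMSE, 0)
  expect_equal(m0$R, 1)

  m <- compute_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$MAE, 1 / 3)
  expect_equal(m$RMSE, sqrt(1 / 3))
  expect_equal(m$R, stats::cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(m$R2, m$R^2)
  expect_equal(m$RE, m$RMSE / 2)

  expect_error(compute_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(compute_metrics(1:3, 1:4), "length")
  expect_error(compute_metrics(1, 1), "two pairs")
})

test_that("R is invariant under positive affine maps; MAE never exceeds RMSE", {
  set.seed(51)
  for (i in 1:25) {
    a <- rnorm(30, 40, 10)
    c_ <- a + rnorm(30, 0, 5)
    m <- compute_metrics(a, c_)
    expect_lte(m$MAE, m$RMSE + 1e-12)
    expect_gte(m$MAE, 0)
    expect_true(abs(m$R) <= 1 + 1e-12)
    m2 <- compute_metrics(a, 3.2 * c_ + 7)
    expect_equal(m$R, m2$R, tolerance = 1e-12)
    m3 <- compute_metrics(0.5 * a + 2, c_)
    expect_equal(m$R, m3$R, tolerance = 1e-12)
  }
  # equal absolute errors: MAE equals RMSE
  me <- compute_metrics(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(me$MAE, me$RMSE)
})

test_that("metrics commute with min-max scaling as affine theory predicts", {
  set.seed(52)
  a <- rnorm(40, 50, 15)
  c_ <- a + rnorm(40, 0, 6)
  both <- cbind(obs = a, pred = c_)
  np <- fit_minmax(cbind(v = c(a, c_)))
  span <- unname(np$s_max - np$s_min)
  an <- (a - np$s_min) / span
  cn <- (c_ - np$s_min) / span
  raw <- compute_metrics(a, c_)
  nrm <- compute_metrics(an, cn)
  expect_equal(raw$MAE, nrm$MAE * span)
  expect_equal(raw$RMSE, nrm$RMSE * span)
  expect_equal(raw$R, nrm$R)
})

test_that("stage reports cover three stages with coherent cells", {
  set.seed(53)
  s <- make_series(rnorm(150, 45, 10))
  sm <- build_supervised(s)
  split <- chronological_split(sm)
  fit <- fit_forecaster(sm, split, preset_model_spec(
    "ANN4", config = train_config("lm", max_epochs = 15, seed = 4)))
  rep <- stage_report(fit, sm, split)
  expect_equal(rep$stage, c("training", "verification", "predicting"))
  expect_true(all(rep$MAE <= rep$RMSE + 1e-12))
  expect_true(all(rep$R >= -1 & rep$R <= 1))
  expect_equal(rep$n, unname(lengths(split)))

  # noise-free linear fit: essentially zero error everywhere
  gen <- generate_daily_series(synthetic_config(n_days = 300, noise_sd = 0))
  sml <- build_supervised(gen$series, pm_lags = 0, met_vars = c("minat", "maxap"))
  spl <- chronological_split(sml)
  lfit <- fit_forecaster(sml, spl, model_spec(
    "lin", met_vars = c("minat", "maxap"), pm_lags = 0, n_hidden = 2,
    hidden_act = "purelin", output_act = "purelin",
    config = train_config("lm", max_epochs = 100, goal = 1e-22, seed = 6)))
  lrep <- stage_report(lfit, sml, spl)
  expect_lt(max(lrep$RMSE), 1e-6)

  tab <- performance_table(list(fit, lfit)[1], sm, split)
  expect_equal(nrow(tab), 3L)
})
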