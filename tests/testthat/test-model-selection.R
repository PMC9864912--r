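test_that("input ranking recovers planted correlation structure", {
  set.seed(41)
  n <- 2000
  z <- rnorm(n)
  planted <- c(0.9, 0.5, 0.1)
  x <- sapply(planted, function(r) r * z + sqrt(1 - r^2) * rnorm(n))
  noise <- rnorm(n)
  sm <- list(x = cbind(strong = x[, 1], medium = x[, 2], weak = x[, 3],
                       indep = noise, self = z),
             y = z)
  class(sm) <- "supervised_matrix"
  tab <- rank_inputs_by_correlation(sm)
  expect_equal(tab$variable[1], "self")
  expect_equal(tab$r[1], 1)
  expect_equal(tab$variable[2:4], c("strong", "medium", "weak"))
  expect_lt(tab$abs_r[tab$variable == "indep"], 0.1)
  expect_true(tab$significant_0.01[1])

  # constant columns are flagged and ranked last
  sm$x <- cbind(sm$x, flat = rep(1, n))
  tab2 <- rank_inputs_by_correlation(sm)
  expect_equal(tab2$variable[nrow(tab2)], "flat")
  expect_true(is.na(tab2$r[nrow(tab2)]))
})

test_that("grid search produces a sorted, deterministic leaderboard", {
  set.seed(42)
  s <- make_series(rnorm(140, 45, 10))
  sm <- build_supervised(s)
  split <- chronological_split(sm)
  space <- search_space(
    input_sets = list(A = list(met_vars = character(0), pm_lags = 0,
                               use_wavelet = FALSE)),
    hidden_sizes = c(1, 3), algorithms = "lm")
  lb <- grid_search(sm, split, space, replicates = 2, seed = 7,
                    config = train_config(max_epochs = 8))
  expect_equal(nrow(lb), 2L)
  expect_true(!is.unsorted(lb$mean_val_rmse))
  expect_equal(lb$rank, 1:2)

  lb2 <- grid_search(sm, split, space, replicates = 2, seed = 7,
                     config = train_config(max_epochs = 8))
  expect_identical(lb$mean_val_rmse, lb2$mean_val_rmse)

  single <- search_space(input_sets = list(A = list(met_vars = character(0),
                                                    pm_lags = 0)),
                         hidden_sizes = 2, algorithms = "rp")
  lb3 <- grid_search(sm, split, single, replicates = 1, seed = 1,
                     config = train_config(max_epochs = 5))
  expect_equal(nrow(lb3), 1L)
  expect_error(search_space(hidden_sizes = integer(0)), "non-empty")
  expect_error(search_space(algorithms = "trainfoo"), "valid ids")
})

test_that("grid search prefers the input set that generated the data", {
  wins <- 0
  for (sd in 1:10) {
    gen <- generate_daily_series(synthetic_config(n_days = 300, phi = 0,
                                                  noise_sd = 1, seed = sd))
    sm <- build_supervised(gen$series, pm_lags = 0,
                           met_vars = c("minat", "maxap", "mrh"))
    split <- chronological_split(sm)
    space <- search_space(
      input_sets = list(
        correct = list(met_vars = c("minat", "maxap"), pm_lags = integer(0)),
        wrong = list(met_vars = "mrh", pm_lags = integer(0))),
      hidden_sizes = 2, algorithms = "lm",
      activation_pairs = list(c("purelin", "purelin")))
    lb <- grid_search(sm, split, space, replicates = 1, seed = sd,
                      config = train_config(max_epochs = 30))
    if (lb$input_set[1] == "correct") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("k-fold cross-validation partitions rows and recovers linear data", {
  set.seed(43)
  s <- make_series(rnorm(80, 45, 10))
  sm <- build_supervised(s)
  spec <- model_spec("cv", met_vars = character(0), pm_lags = 0, n_hidden = 2,
                     config = train_config("lm", max_epochs = 5))
  cv <- kfold_cv(sm, spec, k = 5, seed = 2)
  expect_equal(sort(unique(cv$fold_of)), 1:5)
  expect_equal(length(cv$fold_of), length(sm$y))
  expect_equal(sum(cv$per_fold$n), length(sm$y))

  # leave-one-out: every fold has one test row
  cv1 <- kfold_cv(sm, spec, k = length(sm$y), seed = 2)
  expect_true(all(cv1$per_fold$n == 1))
  expect_error(kfold_cv(sm, spec, k = 1), "2 <= k")

  # noise-free linear process: near-zero fold RMSE
  gen <- generate_daily_series(synthetic_config(n_days = 200, noise_sd = 0))
  sml <- build_supervised(gen$series, pm_lags = 0, met_vars = c("minat", "maxap"))
  lspec <- model_spec("lin", met_vars = c("minat", "maxap"), pm_lags = 0,
                      n_hidden = 2, hidden_act = "purelin",
                      output_act = "purelin",
                      config = train_config("lm", max_epochs = 100, goal = 1e-22))
  cvl <- kfold_cv(sml, lspec, k = 5, seed = 3)
  expect_lt(cvl$mean["RMSE"], 1e-6)

  # random scheme is deterministic under seed
  cva <- kfold_cv(sm, spec, k = 4, scheme = "random", seed = 9)
  cvb <- kfold_cv(sm, spec, k = 4, scheme = "random", seed = 9)
  expect_identical(cva$fold_of, cvb$fold_of)
})
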