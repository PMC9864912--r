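test_that("Levenberg-Marquardt reaches the least-squares optimum on linear data", {
  prob <- make_linear_problem(n = 60, seed = 1, noise = 0.05)
  m <- init_model(3, 2, seed = 2, hidden_act = "purelin", output_act = "purelin")
  res <- train(m, prob$X, prob$y, train_config("lm", max_epochs = 300, goal = 1e-20))
  sse_net <- sum((prob$y - forward(res$model, prob$X))^2)
  sse_ols <- sum(residuals(stats::lm(prob$y ~ prob$X))^2)
  expect_lt(abs(sse_net - sse_ols), 1e-8)
})

test_that("degenerate stopping behaviour is reported faithfully", {
  prob <- make_linear_problem(n = 30, seed = 3)
  # zero learning rate: nothing moves, budget is exhausted
  m <- init_model(3, 2, seed = 4)
  res <- train(m, prob$X, prob$y, train_config("gd", lr = 0, max_epochs = 5))
  expect_identical(pack_params(res$model), pack_params(m))
  expect_equal(res$stop_reason, "max_epochs")
  expect_equal(res$epochs, 5L)

  # already below goal: zero epochs, reason "goal"
  m2 <- init_model(3, 2, seed = 4)
  res2 <- train(m2, prob$X, prob$y,
                train_config("gd", goal = 1e6, max_epochs = 50))
  expect_equal(res2$stop_reason, "goal")
  expect_equal(res2$epochs, 0L)

  expect_error(train_config("trainfoo"),
               "gd, gdm, gdx, rp, scg, cgf, cgp, cgb, bfg, oss, lm, br")
})

test_that("all twelve trainers reduce the global error on a smooth toy problem", {
  set.seed(22)
  X <- matrix(runif(180), 60, 3)
  y <- tanh(drop(X %*% c(1, -1, 0.5))) * 0.4 + 0.3
  for (alg in list_algorithms()) {
    m <- init_model(3, 4, seed = 3)
    res <- train(m, X, y, train_config(alg, max_epochs = 200))
    expect_lt(min(res$err_traj), res$err_traj[1],
              label = paste0("final E (", alg, ")"))
    expect_true(all(is.finite(res$err_traj)), info = alg)
  }
})

test_that("training is deterministic under an identical configuration", {
  set.seed(23)
  X <- matrix(runif(90), 30, 3)
  y <- drop(X %*% c(0.2, 0.1, -0.4)) + 0.5
  for (alg in c("lm", "br", "rp", "scg")) {
    cfg <- train_config(alg, max_epochs = 30, seed = 99)
    r1 <- train(init_model(3, 3, seed = 7), X, y, cfg)
    r2 <- train(init_model(3, 3, seed = 7), X, y, cfg)
    expect_identical(pack_params(r1$model), pack_params(r2$model), info = alg)
    expect_identical(r1$err_traj, r2$err_traj, info = alg)
  }
})

test_that("Bayesian regularization keeps gamma in [0, N] and shrinks weights on noise", {
  set.seed(24)
  X <- matrix(runif(180), 60, 3)
  shrunk <- 0
  for (s in 1:10) {
    y <- rnorm(60)                      # pure noise targets
    mb <- init_model(3, 4, seed = s)
    ml <- init_model(3, 4, seed = s)
    rb <- train(mb, X, y, train_config("br", max_epochs = 40))
    rl <- train(ml, X, y, train_config("lm", max_epochs = 40))
    N <- length(pack_params(mb))
    expect_gte(rb$gamma, 0)
    expect_lte(rb$gamma, N)
    expect_gt(rb$alpha, 0)
    expect_gt(rb$beta, 0)
    if (sum(pack_params(rb$model)^2) <= sum(pack_params(rl$model)^2)) {
      shrunk <- shrunk + 1
    }
  }
  expect_gte(shrunk, 6)                 # majority across 10 seeds
})

test_that("validation-based early stopping halts on stalled progress", {
  set.seed(25)
  X <- matrix(runif(120), 40, 3)
  y <- rnorm(40)
  m <- init_model(3, 3, seed = 1)
  # frozen parameters: the validation error can never improve
  res <- train(m, X[1:30, ], y[1:30],
               train_config("gd", lr = 0, max_epochs = 500, patience = 10),
               val_rows = X[31:40, ], val_targets = y[31:40])
  expect_equal(res$stop_reason, "stall")
  expect_equal(res$epochs, 10L)
})
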