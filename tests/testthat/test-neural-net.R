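test_that("activation values and derivatives follow their definitions", {
  expect_equal(activation("logsig", 0)$value, 0.5)
  expect_equal(activation("tansig", 0)$value, 0)
  expect_equal(activation("purelin", 3.7)$value, 3.7)
  expect_equal(activation("poslin", -2)$value, 0)
  expect_equal(activation("poslin", 3)$value, 3)
  expect_error(activation("relu6", 1), "unknown activation")

  # derivatives against central differences, away from the poslin kink
  for (nm in c("logsig", "tansig", "purelin", "poslin")) {
    for (r in c(-1.3, -0.4, 0.6, 2.1)) {
      f <- function(z) activation(nm, z)$value
      expect_equal(activation(nm, r)$derivative,
                   (f(r + 1e-6) - f(r - 1e-6)) / 2e-6, tolerance = 1e-6)
    }
  }
  expect_equal(activation("poslin", 0)$derivative, 0)
})

test_that("init_model is reproducible, dimensioned, and Nguyen-Widrow scaled", {
  m1 <- init_model(17, 15, seed = 42)
  m2 <- init_model(17, 15, seed = 42)
  expect_identical(m1, m2)
  expect_equal(dim(m1$W1), c(15L, 17L))

  m <- init_model(6, 9, scheme = "nguyen_widrow", seed = 3)
  expect_equal(unname(sqrt(rowSums(m$W1^2))), rep(0.7 * 9^(1 / 6), 9))

  u <- init_model(4, 3, scheme = "uniform", seed = 1)
  expect_true(all(abs(pack_params(u)) <= 0.5))
  expect_error(init_model(0, 5), ">= 1")
})

test_that("forward pass reproduces hand-computed outputs", {
  # zero weights, purelin output: constant prediction b2
  m0 <- mlp_model(matrix(0, 3, 2), rep(0, 3), rep(0, 3), 1.5)
  expect_equal(forward(m0, matrix(rnorm(10), 5, 2)), rep(1.5, 5))

  # 1-1-1 tansig-purelin, w1 = 1, b1 = 0, w2 = 2, b2 = 1
  m <- mlp_model(matrix(1, 1, 1), 0, 2, 1)
  expect_equal(forward(m, matrix(0)), 1)
  expect_equal(forward(m, matrix(1)), 2 * tanh(1) + 1)

  expect_error(forward(m, matrix(1, 1, 3)), "expects")
})

test_that("global error is the mean squared deviation", {
  expect_equal(global_error(c(1, 2), c(1, 2)), 0)
  expect_equal(global_error(c(1, 0), c(0, 0)), 0.5)
  expect_error(global_error(numeric(0), numeric(0)), "empty")
  expect_error(global_error(1:3, 1:2), "length")
})

test_that("backpropagation matches finite differences for every activation pair", {
  set.seed(13)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  for (ha in c("logsig", "tansig", "purelin", "poslin")) {
    for (oa in c("purelin", "tansig", "logsig", "poslin")) {
      m <- init_model(3, 4, seed = 17, hidden_act = ha, output_act = oa)
      g <- pack_gradient(backprop_gradient(m, X, y))
      fn <- function(th) global_error(y, forward(unpack_params(th, m), X))
      ng <- num_gradient(fn, pack_params(m))
      expect_lt(max(abs(g - ng) / (abs(ng) + 1e-8)), 1e-6)
    }
  }
})

test_that("gradient is zero at an interpolating point and scales with residuals", {
  set.seed(14)
  m <- init_model(2, 3, seed = 5)
  X <- matrix(rnorm(10), 5, 2)
  y <- forward(m, X)                     # zero residual
  g <- pack_gradient(backprop_gradient(m, X, y))
  expect_equal(max(abs(g)), 0)

  # purelin output: doubling residuals doubles the output-layer gradient
  y2 <- y - 0.3
  y3 <- y - 0.6
  g2 <- backprop_gradient(m, X, y2)
  g3 <- backprop_gradient(m, X, y3)
  expect_equal(g3$W2, 2 * g2$W2)
  expect_equal(g3$b2, 2 * g2$b2)
})

test_that("regularized-objective gradient includes the weight-decay term", {
  set.seed(15)
  m <- init_model(3, 2, seed = 8)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  a <- 0.3; b <- 2
  g <- pack_gradient(backprop_gradient(m, X, y, objective = "br",
                                       alpha = a, beta = b))
  fn <- function(th) {
    mm <- unpack_params(th, m)
    b * sum((y - forward(mm, X))^2) + a * sum(th^2)
  }
  ng <- num_gradient(fn, pack_params(m))
  expect_lt(max(abs(g - ng) / (abs(ng) + 1e-6)), 1e-6)
})

test_that("the output Jacobian matches finite differences", {
  set.seed(16)
  m <- init_model(2, 3, seed = 9, hidden_act = "logsig", output_act = "tansig")
  X <- matrix(rnorm(8), 4, 2)
  J <- mlp_jacobian(m, X)
  th <- pack_params(m)
  for (i in seq_along(th)) {
    tp <- th; tm <- th
    tp[i] <- tp[i] + 1e-6; tm[i] <- tm[i] - 1e-6
    ndi <- (forward(unpack_params(tp, m), X) - forward(unpack_params(tm, m), X)) / 2e-6
    expect_equal(J[, i], ndi, tolerance = 1e-5)
  }
})
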