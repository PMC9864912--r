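# One-hidden-layer feed-forward network (MLP) with a registry of twelve
# batch training algorithms: first-order gradient descent variants, Rprop,
# conjugate-gradient and quasi-Newton methods, Levenberg-Marquardt, and
# Bayesian regularization (evidence framework on top of LM).
#
# Training operates on min-max normalized data; the error goal (default
# 1e-5) is a mean squared error on that normalized scale.

.algorithms <- c("gd", "gdm", "gdx", "rp", "scg", "cgf", "cgp", "cgb",
                 "bfg", "oss", "lm", "br")

# --- activations ----------------------------------------------------------

#' Activation functions and their derivatives
#'
#' The four transfer functions used in the networks: `logsig` (logistic
#' sigmoid, range (0,1)), `tansig` (hyperbolic tangent, range (-1,1)),
#' `purelin` (identity) and `poslin` (rectified linear; derivative at 0
#' defined as 0).
#'
#' @param name One of `"logsig"`, `"tansig"`, `"purelin"`, `"poslin"`.
#' @param r Finite numeric input(s).
#' @return List with `value` and `derivative` (same shape as `r`).
#' @export
activation <- function(name, r) {
  f <- act_fun(name)
  list(value = f$f(r), derivative = f$df(r))
}

act_fun <- function(name) {
  switch(name,
    logsig = list(
      f = function(r) 1 / (1 + exp(-r)),
      df = function(r) { s <- 1 / (1 + exp(-r)); s * (1 - s) }
    ),
    tansig = list(
      f = function(r) tanh(r),
      df = function(r) 1 - tanh(r)^2
    ),
    purelin = list(
      f = function(r) r,
      df = function(r) { r[] <- 1; r }
    ),
    poslin = list(
      f = function(r) pmax(r, 0),
      df = function(r) (r > 0) * 1
    ),
    stop("unknown activation '", name,
         "'; supported: logsig, tansig, purelin, poslin", call. = FALSE)
  )
}

# --- model ----------------------------------------------------------------

#' Construct an MLP model object
#'
#' @param W1 Hidden-layer weight matrix (`n_hidden x n_inputs`).
#' @param b1 Hidden biases (length `n_hidden`).
#' @param W2 Output weights (length `n_hidden`).
#' @param b2 Output bias (scalar).
#' @param hidden_act,output_act Activation names (see [activation()]).
#' @return An `mlp_model` object.
#' @export
mlp_model <- function(W1, b1, W2, b2, hidden_act = "tansig",
                      output_act = "purelin") {
  W1 <- as.matrix(W1)
  W2 <- as.numeric(W2)
  b1 <- as.numeric(b1)
  b2 <- as.numeric(b2)
  act_fun(hidden_act); act_fun(output_act)
  if (nrow(W1) != length(b1) || nrow(W1) != length(W2) || length(b2) != 1L) {
    stop("inconsistent parameter dimensions", call. = FALSE)
  }
  if (!all(is.finite(W1), is.finite(b1), is.finite(W2), is.finite(b2))) {
    stop("parameters must be finite", call. = FALSE)
  }
  out <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
              hidden_act = hidden_act, output_act = output_act)
  class(out) <- "mlp_model"
  out
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("mlp_model: ", ncol(x$W1), ":", nrow(x$W1), ":1 (",
      x$hidden_act, "-", x$output_act, "), ",
      n_params(x), " parameters\n", sep = "")
  invisible(x)
}

n_params <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + 1L
}

pack_params <- function(model) {
  c(as.vector(model$W1), model$b1, model$W2, model$b2)
}

unpack_params <- function(theta, model) {
  H <- nrow(model$W1); I <- ncol(model$W1)
  model$W1 <- matrix(theta[seq_len(H * I)], H, I)
  model$b1 <- theta[H * I + seq_len(H)]
  model$W2 <- theta[H * I + H + seq_len(H)]
  model$b2 <- theta[H * I + 2L * H + 1L]
  model
}

#' Initialize an MLP
#'
#' `"nguyen_widrow"` scales each hidden weight row to the norm
#' `0.7 * n_hidden^(1/n_inputs)` and spreads the hidden biases evenly over
#' `[-scale, scale]`; `"uniform"` draws all parameters from U(-0.5, 0.5).
#'
#' @param n_inputs,n_hidden Layer sizes (>= 1).
#' @param scheme `"nguyen_widrow"` (default) or `"uniform"`.
#' @param seed Optional integer seed for reproducible draws.
#' @param hidden_act,output_act Activation names.
#' @return An `mlp_model`.
#' @export
init_model <- function(n_inputs, n_hidden, scheme = c("nguyen_widrow", "uniform"),
                       seed = NULL, hidden_act = "tansig",
                       output_act = "purelin") {
  scheme <- match.arg(scheme)
  n_inputs <- as.integer(n_inputs); n_hidden <- as.integer(n_hidden)
  if (n_inputs < 1L || n_hidden < 1L) {
    stop("n_inputs and n_hidden must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "uniform") {
    W1 <- matrix(stats::runif(n_hidden * n_inputs, -0.5, 0.5), n_hidden, n_inputs)
    b1 <- stats::runif(n_hidden, -0.5, 0.5)
  } else {
    scale <- 0.7 * n_hidden^(1 / n_inputs)
    W1 <- matrix(stats::runif(n_hidden * n_inputs, -1, 1), n_hidden, n_inputs)
    norms <- sqrt(rowSums(W1^2))
    norms[norms == 0] <- 1
    W1 <- W1 * (scale / norms)
    b1 <- if (n_hidden == 1L) 0 else seq(-scale, scale, length.out = n_hidden)
  }
  W2 <- stats::runif(n_hidden, -0.5, 0.5)
  b2 <- stats::runif(1, -0.5, 0.5)
  mlp_model(W1, b1, W2, b2, hidden_act, output_act)
}

forward_full <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$W1)) {
    stop("input has ", ncol(X), " columns but the model expects ",
         ncol(model$W1), call. = FALSE)
  }
  f1 <- act_fun(model$hidden_act); f2 <- act_fun(model$output_act)
  z1 <- X %*% t(model$W1)
  z1 <- sweep(z1, 2, model$b1, "+")
  a1 <- f1$f(z1)
  z2 <- drop(a1 %*% model$W2) + model$b2
  list(z1 = z1, a1 = a1, z2 = z2, q = f2$f(z2),
       f1p = f1$df(z1), f2p = f2$df(z2), X = X)
}

#' Forward pass: network predictions
#'
#' Computes the weighted sums and activations of the hidden and output
#' layers for each row of `rows`.
#'
#' @param model An `mlp_model`.
#' @param rows Predictor matrix (columns must match the model inputs).
#' @return Numeric vector of predictions, one per row.
#' @export
forward <- function(model, rows) {
  forward_full(model, rows)$q
}

#' Global (mean squared) error
#'
#' `E = (1/l) * sum((T - Q)^2)` over the `l` target/prediction pairs.
#'
#' @param targets,predictions Equal-length numeric vectors.
#' @return Non-negative scalar; zero iff the vectors are equal.
#' @export
global_error <- function(targets, predictions) {
  if (length(targets) == 0L) stop("empty target vector", call. = FALSE)
  if (length(targets) != length(predictions)) {
    stop("targets and predictions differ in length", call. = FALSE)
  }
  mean((targets - predictions)^2)
}

#' Backpropagation gradient
#'
#' Gradient of the global mean squared error (or, for
#' `objective = "br"`, of the regularized objective
#' `beta * sum((T-Q)^2) + alpha * sum(theta^2)`) with respect to all
#' parameters.
#'
#' @param model An `mlp_model`.
#' @param rows Predictor matrix.
#' @param targets Target vector.
#' @param objective `"mse"` (default) or `"br"`.
#' @param alpha,beta Regularization hyperparameters (used by `"br"`).
#' @return List with gradients `W1`, `b1`, `W2`, `b2` shaped like the model
#'   parameters.
#' @export
backprop_gradient <- function(model, rows, targets, objective = c("mse", "br"),
                              alpha = 0, beta = 1) {
  objective <- match.arg(objective)
  fw <- forward_full(model, rows)
  l <- length(targets)
  if (length(fw$q) != l) stop("dimension mismatch", call. = FALSE)
  resid <- fw$q - targets
  dEdq <- if (objective == "mse") 2 * resid / l else 2 * beta * resid
  delta2 <- dEdq * fw$f2p                       # length n
  gW2 <- drop(crossprod(fw$a1, delta2))         # H
  gb2 <- sum(delta2)
  delta1 <- (delta2 %*% t(model$W2)) * fw$f1p   # n x H
  gW1 <- crossprod(delta1, fw$X)                # H x I
  gb1 <- colSums(delta1)
  if (objective == "br") {
    gW1 <- gW1 + 2 * alpha * model$W1
    gb1 <- gb1 + 2 * alpha * model$b1
    gW2 <- gW2 + 2 * alpha * model$W2
    gb2 <- gb2 + 2 * alpha * model$b2
  }
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

pack_gradient <- function(g) c(as.vector(g$W1), g$b1, g$W2, g$b2)

# Jacobian of the network output w.r.t. the packed parameters (n x N).
# Used by the Gauss-Newton approximation in lm/br.
mlp_jacobian <- function(model, X) {
  fw <- forward_full(model, X)
  n <- length(fw$q)
  H <- nrow(model$W1); I <- ncol(model$W1)
  N <- H * I + 2L * H + 1L
  J <- matrix(0, n, N)
  hid <- sweep(fw$f1p, 2, model$W2, "*") * fw$f2p   # n x H: dq/dz1
  for (h in seq_len(H)) {
    J[, h + H * (seq_len(I) - 1L)] <- hid[, h] * fw$X
  }
  J[, H * I + seq_len(H)] <- hid                    # b1
  J[, H * I + H + seq_len(H)] <- fw$a1 * fw$f2p     # W2
  J[, N] <- fw$f2p                                  # b2
  J
}

# --- training configuration ----------------------------------------------

#' Training configuration
#'
#' @param algorithm One of the twelve trainer ids: `"gd"` (gradient
#'   descent), `"gdm"` (with momentum), `"gdx"` (momentum + adaptive
#'   learning rate), `"rp"` (resilient backpropagation), `"scg"` (scaled
#'   conjugate gradient), `"cgf"`/`"cgp"`/`"cgb"` (conjugate gradient with
#'   Fletcher-Reeves / Polak-Ribiere updates / Powell-Beale restarts),
#'   `"bfg"` (BFGS quasi-Newton), `"oss"` (one-step secant), `"lm"`
#'   (Levenberg-Marquardt), `"br"` (Bayesian regularization).
#' @param max_epochs Epoch budget (default 1000).
#' @param goal Mean-squared-error goal on the normalized scale
#'   (default 1e-5); training stops once the global error falls below it.
#' @param lr Learning rate for gd/gdm/gdx (default 0.01).
#' @param momentum Momentum coefficient for gdm/gdx (default 0.9).
#' @param lr_inc,lr_dec,max_perf_inc Adaptive learning-rate parameters
#'   (gdx).
#' @param delta0,delta_min,delta_max,eta_plus,eta_minus Rprop step-size
#'   parameters.
#' @param mu0,mu_inc,mu_dec,mu_max Levenberg-Marquardt damping schedule.
#' @param patience Epochs without validation improvement before an early
#'   stop (when a validation set is supplied).
#' @param min_grad Gradient-norm floor; below it training stalls.
#' @param seed Optional seed recorded for reproducibility.
#' @return A `train_config` object.
#' @export
train_config <- function(algorithm = "lm", max_epochs = 1000, goal = 1e-5,
                         lr = 0.01, momentum = 0.9, lr_inc = 1.05,
                         lr_dec = 0.7, max_perf_inc = 1.04, delta0 = 0.07,
                         delta_min = 1e-6, delta_max = 50, eta_plus = 1.2,
                         eta_minus = 0.5, mu0 = 1e-3, mu_inc = 10,
                         mu_dec = 0.1, mu_max = 1e10, patience = 20,
                         min_grad = 1e-10, seed = NULL) {
  if (!is.character(algorithm) || length(algorithm) != 1L ||
      !algorithm %in% .algorithms) {
    stop("unknown training algorithm '", algorithm, "'; valid ids: ",
         paste(.algorithms, collapse = ", "), call. = FALSE)
  }
  if (goal <= 0) stop("goal must be > 0", call. = FALSE)
  max_epochs <- as.integer(max_epochs)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  out <- as.list(environment())
  class(out) <- "train_config"
  out
}

#' List the supported training algorithm ids
#' @return Character vector of the twelve trainer ids.
#' @export
list_algorithms <- function() .algorithms

# --- trainers -------------------------------------------------------------

#' Train an MLP
#'
#' Full-batch training of `model` on normalized data (the trainer does not
#' renormalize).  Stops when the global error drops below `config$goal`
#' (`"goal"`), the epoch budget is exhausted (`"max_epochs"`), or progress
#' stalls -- vanished gradient, exhausted damping, or `config$patience`
#' epochs without validation improvement (`"stall"`).  With a validation
#' set the returned parameters are those with the best validation error.
#'
#' @param model An `mlp_model` (see [init_model()]).
#' @param rows,targets Training predictors and targets.
#' @param config A [train_config()].
#' @param val_rows,val_targets Optional validation set for early stopping.
#' @return A `train_result`: list with `model`, `epochs`, `err_traj`
#'   (global error per epoch, element 1 = initial), `stop_reason`, and for
#'   `"br"` the final `alpha`, `beta`, `gamma` (effective parameters).
#' @export
train <- function(model, rows, targets, config = train_config(),
                  val_rows = NULL, val_targets = NULL) {
  stopifnot(inherits(model, "mlp_model"), inherits(config, "train_config"))
  rows <- as.matrix(rows)
  targets <- as.numeric(targets)
  if (nrow(rows) != length(targets)) {
    stop("rows and targets differ in length", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$algorithm == "lm") {
    return(train_lm(model, rows, targets, config, val_rows, val_targets))
  }
  if (config$algorithm == "br") {
    return(train_br(model, rows, targets, config, val_rows, val_targets))
  }
  train_first_order(model, rows, targets, config, val_rows, val_targets)
}

new_result <- function(model, theta, traj, epochs, reason, extra = NULL) {
  out <- c(list(model = unpack_params(theta, model),
                epochs = epochs, err_traj = traj, stop_reason = reason),
           extra)
  class(out) <- "train_result"
  out
}

#' @export
print.train_result <- function(x, ...) {
  cat("train_result: ", x$epochs, " epochs, stop = ", x$stop_reason,
      ", final E = ", format(x$err_traj[length(x$err_traj)], digits = 6),
      "\n", sep = "")
  invisible(x)
}

# Shared loop for gradient-based trainers.  `stepper(theta, g, E, state)`
# returns list(theta, state); it may consult `loss` through the closure.
train_first_order <- function(model, X, y, config, Xval, yval) {
  loss <- function(theta) global_error(y, forward(unpack_params(theta, model), X))
  grad <- function(theta) {
    pack_gradient(backprop_gradient(unpack_params(theta, model), X, y))
  }
  val_loss <- if (!is.null(Xval)) {
    function(theta) global_error(yval, forward(unpack_params(theta, model), Xval))
  } else NULL

  stepper <- switch(config$algorithm,
    gd = stepper_gd(config), gdm = stepper_gdm(config),
    gdx = stepper_gdx(config), rp = stepper_rp(config),
    scg = stepper_scg(config), cgf = stepper_cg(config, "fr"),
    cgp = stepper_cg(config, "pr"), cgb = stepper_cg(config, "pb"),
    bfg = stepper_bfgs(config), oss = stepper_oss(config))

  theta <- pack_params(model)
  E <- loss(theta)
  traj <- E
  state <- NULL
  reason <- "max_epochs"
  epochs <- 0L
  best_val <- Inf; best_theta <- theta; wait <- 0L
  if (!is.null(val_loss)) best_val <- val_loss(theta)
  for (epoch in seq_len(config$max_epochs)) {
    if (E < config$goal) { reason <- "goal"; break }
    g <- grad(theta)
    if (sqrt(sum(g^2)) < config$min_grad) { reason <- "stall"; break }
    st <- stepper(theta, g, E, state, loss)
    theta <- st$theta; state <- st$state
    E <- loss(theta)
    traj <- c(traj, E)
    epochs <- epoch
    if (!is.null(val_loss)) {
      v <- val_loss(theta)
      if (v < best_val - 1e-12) {
        best_val <- v; best_theta <- theta; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { reason <- "stall"; break }
      }
    }
  }
  if (reason == "max_epochs" && E < config$goal) reason <- "goal"
  final_theta <- if (!is.null(val_loss)) best_theta else theta
  new_result(model, final_theta, traj, epochs, reason)
}

stepper_gd <- function(cfg) {
  function(theta, g, E, state, loss) {
    list(theta = theta - cfg$lr * g, state = state)
  }
}

stepper_gdm <- function(cfg) {
  function(theta, g, E, state, loss) {
    v <- if (is.null(state)) numeric(length(theta)) else state$v
    v <- cfg$momentum * v - (1 - cfg$momentum) * cfg$lr * g
    list(theta = theta + v, state = list(v = v))
  }
}

stepper_gdx <- function(cfg) {
  function(theta, g, E, state, loss) {
    if (is.null(state)) state <- list(v = numeric(length(theta)), lr = cfg$lr)
    v <- cfg$momentum * state$v - (1 - cfg$momentum) * state$lr * g
    cand <- theta + v
    E_new <- loss(cand)
    if (E_new > E * cfg$max_perf_inc) {         # reject, shrink, reset momentum
      state$lr <- state$lr * cfg$lr_dec
      state$v <- numeric(length(theta))
      list(theta = theta, state = state)
    } else {
      if (E_new < E) state$lr <- state$lr * cfg$lr_inc
      state$v <- v
      list(theta = cand, state = state)
    }
  }
}

stepper_rp <- function(cfg) {
  function(theta, g, E, state, loss) {
    if (is.null(state)) {
      state <- list(delta = rep(cfg$delta0, length(theta)),
                    g_prev = numeric(length(theta)))
    }
    same <- g * state$g_prev
    state$delta <- ifelse(same > 0, pmin(state$delta * cfg$eta_plus, cfg$delta_max),
                   ifelse(same < 0, pmax(state$delta * cfg$eta_minus, cfg$delta_min),
                          state$delta))
    g_eff <- ifelse(same < 0, 0, g)            # iRprop-: no step after a sign flip
    theta <- theta - sign(g_eff) * state$delta
    state$g_prev <- g_eff
    list(theta = theta, state = state)
  }
}

# Moller's scaled conjugate gradient (one iteration per epoch).
stepper_scg <- function(cfg) {
  sigma0 <- 5e-5
  function(theta, g, E, state, loss) {
    n <- length(theta)
    if (is.null(state)) {
      state <- list(lambda = 5e-7, lambda_bar = 0, p = -g, r = -g,
                    success = TRUE, k = 1L)
    }
    p <- state$p; r <- state$r
    p2 <- sum(p^2)
    if (p2 < 1e-300) return(list(theta = theta, state = NULL))
    if (state$success) {
      sigma <- sigma0 / sqrt(p2)
      # directional curvature from a gradient difference along p
      gp <- grad_exact(loss, theta + sigma * p)
      s <- (gp - g) / sigma
      state$delta <- sum(p * s)
    }
    delta <- state$delta + (state$lambda - state$lambda_bar) * p2
    if (delta <= 0) {
      state$lambda_bar <- 2 * (state$lambda - delta / p2)
      delta <- -delta + state$lambda * p2
      state$lambda <- state$lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    cand <- theta + alpha * p
    E_new <- loss(cand)
    Delta <- 2 * delta * (E - E_new) / mu^2
    if (Delta >= 0) {                          # successful step
      r_new <- -grad_exact(loss, cand)
      state$lambda_bar <- 0
      state$success <- TRUE
      if (state$k %% n == 0L) {
        p <- r_new                              # restart
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      state$p <- p; state$r <- r_new; state$k <- state$k + 1L
      if (Delta >= 0.75) state$lambda <- state$lambda / 4
      theta <- cand
    } else {
      state$lambda_bar <- state$lambda
      state$success <- FALSE
    }
    if (Delta < 0.25) state$lambda <- state$lambda + state$delta * (1 - Delta) / p2
    list(theta = theta, state = state)
  }
}

# scg needs gradients at trial points; recover them from the data bound in
# the loss closure's environment.
grad_exact <- function(loss, theta) {
  env <- environment(loss)
  pack_gradient(backprop_gradient(unpack_params(theta, env$model),
                                  env$X, env$y))
}

# Backtracking line search with step-size memory shared by cg/bfg/oss.
line_search <- function(loss, theta, d, E0, step0) {
  a <- step0
  for (i in 1:30) {
    cand <- theta + a * d
    E_new <- loss(cand)
    if (is.finite(E_new) && E_new < E0) {
      return(list(theta = cand, step = a, ok = TRUE))
    }
    a <- a / 2
  }
  list(theta = theta, step = step0, ok = FALSE)
}

stepper_cg <- function(cfg, variant) {
  function(theta, g, E, state, loss) {
    if (is.null(state)) {
      state <- list(g_prev = NULL, d = NULL, step = 1, restart = TRUE)
    }
    if (state$restart || is.null(state$d)) {
      d <- -g
    } else {
      gg_prev <- sum(state$g_prev^2)
      beta <- switch(variant,
        fr = sum(g^2) / gg_prev,
        pr = max(0, sum(g * (g - state$g_prev)) / gg_prev),
        pb = {
          # Powell-Beale: restart when successive gradients are far from
          # orthogonal, otherwise a Polak-Ribiere-type update
          if (abs(sum(g * state$g_prev)) >= 0.2 * sum(g^2)) NA_real_
          else max(0, sum(g * (g - state$g_prev)) / gg_prev)
        })
      d <- if (is.na(beta)) -g else -g + beta * state$d
      if (sum(d * g) > -1e-12 * sqrt(sum(d^2)) * sqrt(sum(g^2))) d <- -g
    }
    ls <- line_search(loss, theta, d, E, state$step)
    state$g_prev <- g
    state$d <- d
    state$restart <- !ls$ok
    state$step <- if (ls$ok) ls$step * 2 else state$step / 2
    list(theta = ls$theta, state = state)
  }
}

stepper_bfgs <- function(cfg) {
  function(theta, g, E, state, loss) {
    n <- length(theta)
    if (is.null(state)) state <- list(Hinv = diag(n), g_prev = NULL,
                                      theta_prev = NULL, step = 1)
    if (!is.null(state$g_prev)) {
      s <- theta - state$theta_prev
      yv <- g - state$g_prev
      sy <- sum(s * yv)
      if (sy > 1e-10) {
        rho <- 1 / sy
        I_n <- diag(n)
        A <- I_n - rho * outer(s, yv)
        state$Hinv <- A %*% state$Hinv %*% t(A) + rho * outer(s, s)
      } else {
        state$Hinv <- diag(n)
      }
    }
    d <- -drop(state$Hinv %*% g)
    if (sum(d * g) >= 0) { d <- -g; state$Hinv <- diag(n) }
    ls <- line_search(loss, theta, d, E, state$step)
    state$theta_prev <- theta
    state$g_prev <- g
    state$step <- if (ls$ok) min(ls$step * 2, 1) else state$step / 2
    list(theta = ls$theta, state = state)
  }
}

stepper_oss <- function(cfg) {
  function(theta, g, E, state, loss) {
    if (is.null(state)) state <- list(g_prev = NULL, theta_prev = NULL, step = 1)
    if (is.null(state$g_prev)) {
      d <- -g
    } else {
      s <- theta - state$theta_prev
      yv <- g - state$g_prev
      sy <- sum(s * yv)
      if (sy <= 1e-12) {
        d <- -g
      } else {
        sg <- sum(s * g); yg <- sum(yv * g)
        A <- -(1 + sum(yv^2) / sy) * sg / sy + yg / sy
        B <- sg / sy
        d <- -g + A * s + B * yv
        if (sum(d * g) >= 0) d <- -g
      }
    }
    ls <- line_search(loss, theta, d, E, state$step)
    state$theta_prev <- theta
    state$g_prev <- g
    state$step <- if (ls$ok) ls$step * 2 else state$step / 2
    list(theta = ls$theta, state = state)
  }
}

# --- Levenberg-Marquardt --------------------------------------------------

train_lm <- function(model, X, y, config, Xval, yval) {
  theta <- pack_params(model)
  n <- length(y)
  val_loss <- if (!is.null(Xval)) {
    function(th) global_error(yval, forward(unpack_params(th, model), Xval))
  } else NULL
  sse <- function(th) sum((y - forward(unpack_params(th, model), X))^2)
  mu <- config$mu0
  S <- sse(theta)
  traj <- S / n
  reason <- "max_epochs"
  epochs <- 0L
  best_val <- if (!is.null(val_loss)) val_loss(theta) else Inf
  best_theta <- theta; wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    if (S / n < config$goal) { reason <- "goal"; break }
    m_cur <- unpack_params(theta, model)
    J <- mlp_jacobian(m_cur, X)
    r <- y - forward(m_cur, X)
    gnorm <- 2 * sqrt(sum((crossprod(J, r))^2))
    if (gnorm < config$min_grad) { reason <- "stall"; break }
    A <- crossprod(J)
    Jtr <- crossprod(J, r)
    accepted <- FALSE
    while (mu <= config$mu_max) {
      delta <- tryCatch(solve(A + mu * diag(ncol(A)), Jtr),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        S_new <- sse(cand)
        if (is.finite(S_new) && S_new < S) {
          theta <- cand; S <- S_new
          mu <- max(mu * config$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_inc
    }
    if (!accepted) { reason <- "stall"; break }
    traj <- c(traj, S / n)
    epochs <- epoch
    if (!is.null(val_loss)) {
      v <- val_loss(theta)
      if (v < best_val - 1e-12) { best_val <- v; best_theta <- theta; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= config$patience) { reason <- "stall"; break }
      }
    }
  }
  if (reason == "max_epochs" && S / n < config$goal) reason <- "goal"
  final_theta <- if (!is.null(val_loss)) best_theta else theta
  new_result(model, final_theta, traj, epochs, reason)
}

# --- Bayesian regularization ---------------------------------------------

#' Bayesian-regularization training (trainbr)
#'
#' Minimizes `F = beta * E_D + alpha * E_W` (`E_D` = sum of squared errors,
#' `E_W` = sum of squared parameters) by Levenberg-Marquardt steps, with
#' `alpha`, `beta` re-estimated each epoch from the evidence approximation:
#' `gamma = N - 2 * alpha * tr(H^-1)`, `alpha = gamma / (2 E_W)`,
#' `beta = (n - gamma) / (2 E_D)`, where `H = 2 beta J'J + 2 alpha I` is
#' the Gauss-Newton Hessian of `F`, `N` the parameter count and `n` the
#' sample count.  `gamma` is the effective number of well-determined
#' parameters, clamped to `[0, N]`.
#'
#' Reachable through [train()] with `algorithm = "br"`.
#'
#' @inheritParams train
#' @return A `train_result` with final `alpha`, `beta`, `gamma`.
#' @export
train_br <- function(model, rows, targets, config = train_config("br"),
                     val_rows = NULL, val_targets = NULL) {
  X <- as.matrix(rows); y <- as.numeric(targets)
  theta <- pack_params(model)
  n <- length(y)
  N <- length(theta)
  alpha <- 0; beta <- 1
  sse <- function(th) sum((y - forward(unpack_params(th, model), X))^2)
  objective <- function(th, a, b) b * sse(th) + a * sum(th^2)
  mu <- config$mu0
  E_D <- sse(theta)
  traj <- E_D / n
  reason <- "max_epochs"
  epochs <- 0L
  gamma <- N
  for (epoch in seq_len(config$max_epochs)) {
    if (E_D / n < config$goal) { reason <- "goal"; break }
    m_cur <- unpack_params(theta, model)
    J <- mlp_jacobian(m_cur, X)
    r <- y - forward(m_cur, X)
    A <- crossprod(J)
    Jtr <- crossprod(J, r)
    Fv <- beta * E_D + alpha * sum(theta^2)
    accepted <- FALSE
    while (mu <= config$mu_max) {
      lhs <- beta * A + (alpha + mu) * diag(N)
      rhs <- beta * Jtr - alpha * theta
      delta <- tryCatch(solve(lhs, rhs), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        F_new <- objective(cand, alpha, beta)
        if (is.finite(F_new) && F_new < Fv) {
          theta <- cand
          mu <- max(mu * config$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_inc
    }
    if (!accepted) { reason <- "stall"; break }
    E_D <- sse(theta)
    E_W <- sum(theta^2)
    # evidence update on the accepted point (re-linearized Hessian)
    m_cur <- unpack_params(theta, model)
    J <- mlp_jacobian(m_cur, X)
    H <- 2 * beta * crossprod(J) + 2 * alpha * diag(N)
    trHinv <- tryCatch(sum(diag(solve(H))), error = function(e) NA_real_)
    if (is.finite(trHinv)) {
      gamma <- min(max(N - 2 * alpha * trHinv, 0), N)
      if (E_W > 1e-300) alpha <- max(gamma / (2 * E_W), 1e-12)
      if (E_D > 1e-300) beta <- max((n - gamma) / (2 * E_D), 1e-12)
    }
    traj <- c(traj, E_D / n)
    epochs <- epoch
  }
  if (reason == "max_epochs" && E_D / n < config$goal) reason <- "goal"
  new_result(model, theta, traj, epochs, reason,
             extra = list(alpha = alpha, beta = beta, gamma = gamma))
}
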