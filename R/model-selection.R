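# Model-selection machinery: correlation-based input ranking, grid search
# over structures / trainers / activation pairs, and k-fold
# cross-validation with contiguous blocks for time series.

#' Rank candidate inputs by correlation with the next-day target
#'
#' Pearson correlation of every predictor column with the target, with a
#' two-sided significance test, sorted by decreasing `|r|`.  Constant
#' columns are undefined (`NA`) and ranked last.
#'
#' @param matrix A `supervised_matrix` (>= 3 rows).
#' @return Data frame: variable, r, abs_r, p_value, significant_0.01.
#' @export
rank_inputs_by_correlation <- function(matrix) {
  stopifnot(inherits(matrix, "supervised_matrix"))
  if (length(matrix$y) < 3L) stop("need at least 3 rows", call. = FALSE)
  cols <- colnames(matrix$x)
  res <- lapply(cols, function(cn) {
    x <- matrix$x[, cn]
    if (stats::sd(x) == 0) {
      return(data.frame(variable = cn, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(x, matrix$y, alternative = "two.sided")
    data.frame(variable = cn, r = unname(ct$estimate), p_value = ct$p.value)
  })
  tab <- do.call(rbind, res)
  tab$abs_r <- abs(tab$r)
  tab$significant_0.01 <- !is.na(tab$p_value) & tab$p_value < 0.01
  tab <- tab[order(-tab$abs_r, na.last = TRUE), c("variable", "r", "abs_r",
                                                  "p_value", "significant_0.01")]
  rownames(tab) <- NULL
  tab
}

#' Define a model-selection search space
#'
#' @param input_sets Named list; each element is a list with `met_vars`,
#'   `pm_lags` and `use_wavelet`.  Defaults to the eight presets of
#'   [preset_model_spec()].
#' @param hidden_sizes Hidden-layer sizes to try (default 1..21).
#' @param algorithms Trainer ids (default all twelve).
#' @param activation_pairs List of `c(hidden, output)` activation names
#'   (default tansig-purelin).
#' @return A `search_space` object.
#' @export
search_space <- function(input_sets = NULL, hidden_sizes = 1:21,
                         algorithms = list_algorithms(),
                         activation_pairs = list(c("tansig", "purelin"))) {
  if (is.null(input_sets)) {
    ids <- c("ANN1", "ANN2", "ANN3", "ANN4", "WANN1", "WANN2", "WANN3", "WANN4")
    input_sets <- lapply(ids, function(id) {
      sp <- preset_model_spec(id)
      list(met_vars = sp$met_vars, pm_lags = sp$pm_lags,
           use_wavelet = sp$use_wavelet)
    })
    names(input_sets) <- ids
  }
  if (length(input_sets) == 0L || length(hidden_sizes) == 0L ||
      length(algorithms) == 0L || length(activation_pairs) == 0L) {
    stop("every search-space axis must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unlist(algorithms), list_algorithms())
  if (length(bad) > 0L) {
    stop("unknown training algorithm '", bad[1L], "'; valid ids: ",
         paste(list_algorithms(), collapse = ", "), call. = FALSE)
  }
  out <- list(input_sets = input_sets, hidden_sizes = as.integer(hidden_sizes),
              algorithms = algorithms, activation_pairs = activation_pairs)
  class(out) <- "search_space"
  out
}

#' Grid search over the model-selection space
#'
#' Trains every configuration `replicates` times with derived seeds and
#' scores it by the mean verification-stage RMSE (ug/m3).  The leaderboard
#' is sorted ascending by that score; ties prefer fewer hidden neurons,
#' then grid order.
#'
#' @param matrix,split Supervised data and chronological split.
#' @param space A [search_space()].
#' @param replicates Random restarts per configuration (default 3).
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param config Base [train_config()] (algorithm and seed fields are
#'   overridden per configuration).
#' @param wavelet A [wavelet_spec()] for wavelet input sets.
#' @return A `leaderboard` data frame: input_set, n_hidden, algorithm,
#'   hidden_act, output_act, mean_val_rmse, sd_val_rmse, rank.
#' @export
grid_search <- function(matrix, split, space = search_space(), replicates = 3,
                        seed = 1, config = train_config(),
                        wavelet = wavelet_spec()) {
  stopifnot(inherits(space, "search_space"))
  grid <- expand.grid(input_set = names(space$input_sets),
                      n_hidden = space$hidden_sizes,
                      algorithm = unlist(space$algorithms),
                      act_pair = seq_along(space$activation_pairs),
                      stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, nrow(grid), replicates)
  for (i in seq_len(nrow(grid))) {
    iset <- space$input_sets[[grid$input_set[i]]]
    pair <- space$activation_pairs[[grid$act_pair[i]]]
    for (rep_j in seq_len(replicates)) {
      cfg <- config
      cfg$algorithm <- grid$algorithm[i]
      cfg$seed <- (seed + 7919L * (i - 1L) + 104729L * (rep_j - 1L)) %% .Machine$integer.max
      sp <- model_spec(paste0(grid$input_set[i], "/h", grid$n_hidden[i]),
                       met_vars = iset$met_vars, pm_lags = iset$pm_lags,
                       use_wavelet = isTRUE(iset$use_wavelet), wavelet = wavelet,
                       n_hidden = grid$n_hidden[i], hidden_act = pair[1],
                       output_act = pair[2], config = cfg)
      fit <- fit_forecaster(matrix, split, sp)
      pred <- predict_next_day(fit, matrix)
      idx <- split$verification
      scores[i, rep_j] <- sqrt(mean((matrix$y[idx] - pred[idx])^2))
    }
  }
  lb <- data.frame(grid[, c("input_set", "n_hidden", "algorithm")],
                   hidden_act = vapply(space$activation_pairs[grid$act_pair], `[`,
                                       character(1), 1L),
                   output_act = vapply(space$activation_pairs[grid$act_pair], `[`,
                                       character(1), 2L),
                   mean_val_rmse = rowMeans(scores),
                   sd_val_rmse = apply(scores, 1, stats::sd))
  ord <- order(lb$mean_val_rmse, lb$n_hidden, seq_len(nrow(lb)))
  lb <- lb[ord, , drop = FALSE]
  lb$rank <- seq_len(nrow(lb))
  rownames(lb) <- NULL
  class(lb) <- c("leaderboard", "data.frame")
  lb
}

#' k-fold cross-validation of one model specification
#'
#' Partitions the chosen rows into `k` folds -- contiguous blocks by
#' default, which respects the serial order of a time series -- and, for
#' each fold, trains on the remaining rows and evaluates on the fold.
#'
#' @param matrix A `supervised_matrix`.
#' @param spec A [model_spec()].
#' @param k Number of folds (2 <= k <= rows).
#' @param scheme `"contiguous_blocks"` (default) or `"random"`.
#' @param seed Seed for the random scheme and per-fold initializations.
#' @param rows Row indices to cross-validate within (default: all rows).
#' @return List with `per_fold` (fold, MAE, RMSE, R or NA, n) and `mean`
#'   (mean of the per-fold metrics).
#' @export
kfold_cv <- function(matrix, spec, k = 10, scheme = c("contiguous_blocks", "random"),
                     seed = 1, rows = seq_along(matrix$y)) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(matrix, "supervised_matrix"), inherits(spec, "model_spec"))
  k <- as.integer(k)
  n <- length(rows)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= rows", call. = FALSE)
  fold_of <- if (scheme == "contiguous_blocks") {
    as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
  } else {
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  }
  sm <- select_inputs(matrix, spec$met_vars, spec$pm_lags)
  if (spec$use_wavelet) sm <- expand_wavelet_features(sm, spec$wavelet)
  per <- lapply(seq_len(k), function(f) {
    test_rows <- rows[fold_of == f]
    train_rows <- rows[fold_of != f]
    norm <- fit_minmax(cbind(sm$x, target = sm$y)[train_rows, , drop = FALSE])
    xn <- apply_minmax(norm, sm$x)
    yn <- drop(apply_minmax(norm, matrix(sm$y, ncol = 1,
                                         dimnames = list(NULL, "target"))))
    cfg <- spec$config
    cfg$seed <- (seed + 31L * f) %% .Machine$integer.max
    model <- init_model(ncol(xn), spec$n_hidden, seed = cfg$seed,
                        hidden_act = spec$hidden_act, output_act = spec$output_act)
    res <- train(model, xn[train_rows, , drop = FALSE], yn[train_rows], cfg)
    span <- norm$s_max["target"] - norm$s_min["target"]
    pred <- drop(forward(res$model, xn[test_rows, , drop = FALSE])) * span +
      norm$s_min["target"]
    obs <- sm$y[test_rows]
    err <- obs - pred
    r <- if (length(obs) >= 2L && stats::sd(obs) > 0 && stats::sd(pred) > 0) {
      stats::cor(obs, pred)
    } else NA_real_
    data.frame(fold = f, MAE = mean(abs(err)), RMSE = sqrt(mean(err^2)),
               R = r, n = length(obs))
  })
  per_fold <- do.call(rbind, per)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("MAE", "RMSE", "R")], na.rm = TRUE),
       fold_of = fold_of, rows = rows)
}
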