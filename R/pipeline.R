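# Compose data, wavelet and network modules into the ANN / WANN next-day
# forecasters.  A WANN replaces every predictor column by its (level+1)
# reconstructed wavelet components before the network sees it.

#' Specify a forecasting model
#'
#' @param id Model identifier (free text; see [preset_model_spec()] for the
#'   standard ANN1--ANN4 / WANN1--WANN4 presets).
#' @param met_vars Meteorological input variables (possibly empty).
#' @param pm_lags PM2.5 lags used as inputs.
#' @param use_wavelet If `TRUE`, predictors are expanded into wavelet
#'   components (a WANN).
#' @param wavelet A [wavelet_spec()] for the expansion.
#' @param n_hidden Hidden-layer size (>= 1).
#' @param hidden_act,output_act Activation pair (default tansig-purelin).
#' @param config A [train_config()].
#' @return A `model_spec` object.
#' @export
model_spec <- function(id, met_vars = met_schema(), pm_lags = c(0, 1, 2),
                       use_wavelet = FALSE, wavelet = wavelet_spec(),
                       n_hidden = 15, hidden_act = "tansig",
                       output_act = "purelin", config = train_config()) {
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stop("n_hidden must be >= 1", call. = FALSE)
  stopifnot(inherits(wavelet, "wavelet_spec"), inherits(config, "train_config"))
  act_fun(hidden_act); act_fun(output_act)
  out <- list(id = id, met_vars = met_vars, pm_lags = sort(unique(as.integer(pm_lags))),
              use_wavelet = isTRUE(use_wavelet), wavelet = wavelet,
              n_hidden = n_hidden, hidden_act = hidden_act,
              output_act = output_act, config = config)
  class(out) <- "model_spec"
  out
}

#' Standard model presets
#'
#' The eight tested input sets and network structures: ANN1/WANN1 use all
#' fourteen meteorological elements plus PM2.5 at lags 0--2 (structures
#' 17:15:1 and 51:20:1), ANN2/WANN2 the five best-correlated inputs
#' (minat, minap, maxat, PM2.5 t and t-1; 5:19:1 and 15:20:1), ANN3/WANN3
#' minat and PM2.5 t (2:19:1, 6:17:1), ANN4/WANN4 PM2.5 t only
#' (1:21:1, 3:19:1).
#'
#' @param id One of `"ANN1"`..`"ANN4"`, `"WANN1"`..`"WANN4"`.
#' @param config A [train_config()].
#' @param wavelet A [wavelet_spec()] for the WANN presets.
#' @return A [model_spec()].
#' @export
preset_model_spec <- function(id, config = train_config(),
                              wavelet = wavelet_spec()) {
  presets <- list(
    ANN1 = list(met = met_schema(), lags = c(0, 1, 2), hidden = 15),
    ANN2 = list(met = c("minat", "minap", "maxat"), lags = c(0, 1), hidden = 19),
    ANN3 = list(met = "minat", lags = 0, hidden = 19),
    ANN4 = list(met = character(0), lags = 0, hidden = 21),
    WANN1 = list(met = met_schema(), lags = c(0, 1, 2), hidden = 20),
    WANN2 = list(met = c("minat", "minap", "maxat"), lags = c(0, 1), hidden = 20),
    WANN3 = list(met = "minat", lags = 0, hidden = 17),
    WANN4 = list(met = character(0), lags = 0, hidden = 19)
  )
  if (!id %in% names(presets)) {
    stop("unknown preset '", id, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[id]]
  model_spec(id, met_vars = p$met, pm_lags = p$lags,
             use_wavelet = startsWith(id, "WANN"), wavelet = wavelet,
             n_hidden = p$hidden, config = config)
}

# Column names a spec's inputs occupy in a supervised matrix.
input_columns <- function(met_vars, pm_lags) {
  c(met_vars,
    vapply(pm_lags, function(k) if (k == 0L) "pm25_t" else paste0("pm25_tm", k),
           character(1)))
}

# Restrict a supervised matrix to the spec's input variables.
select_inputs <- function(matrix, met_vars, pm_lags) {
  cols <- input_columns(met_vars, pm_lags)
  missing <- setdiff(cols, colnames(matrix$x))
  if (length(missing) > 0L) {
    stop("supervised matrix lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  matrix$x <- matrix$x[, cols, drop = FALSE]
  matrix$met_vars <- intersect(matrix$met_vars, met_vars)
  matrix$pm_lags <- intersect(matrix$pm_lags, pm_lags)
  matrix
}

#' Expand predictors into wavelet components
#'
#' Replaces every predictor column of a supervised matrix by its
#' `level + 1` reconstructed wavelet components (for the default level 2:
#' CA2, CD2, CD1), multiplying the column count by `level + 1`.  The target
#' is untouched.  With a causal spec the leakage-safe prefix decomposition
#' is used.
#'
#' @param matrix A `supervised_matrix`.
#' @param spec A [wavelet_spec()].
#' @return A `supervised_matrix` with expanded predictors; component
#'   columns are named `<column>_ca2`, `<column>_cd2`, `<column>_cd1`, ...
#' @export
expand_wavelet_features <- function(matrix, spec = wavelet_spec()) {
  stopifnot(inherits(matrix, "supervised_matrix"), inherits(spec, "wavelet_spec"))
  if (nrow(matrix$x) < 2^spec$level) {
    stop("matrix has fewer rows than 2^level", call. = FALSE)
  }
  blocks <- lapply(colnames(matrix$x), function(cn) {
    comp <- wavelet_decompose(matrix$x[, cn], spec)$components
    colnames(comp) <- paste0(cn, "_", tolower(colnames(comp)))
    comp
  })
  matrix$x <- do.call(cbind, blocks)
  matrix$wavelet <- spec
  matrix
}

#' Fit an ANN or WANN next-day forecaster
#'
#' Pipeline: restrict to the spec's inputs, optionally expand into wavelet
#' components, fit min--max normalization on the training rows only (or on
#' all rows with `paper_norm = TRUE`), normalize, and train the network on
#' the training stage with the verification stage for early stopping.
#'
#' @param matrix A `supervised_matrix` over all stages.
#' @param split A `stage_split` from [chronological_split()].
#' @param spec A [model_spec()].
#' @param paper_norm If `TRUE`, normalization parameters are fitted on all
#'   rows rather than the training rows only (leaks the later stages'
#'   range; off by default).
#' @return A `fitted_forecaster`: list with `spec`, `norm`, `model`
#'   (trained `mlp_model`), `result` (`train_result`), `split`,
#'   `input_cols`, `paper_norm`.
#' @export
fit_forecaster <- function(matrix, split, spec, paper_norm = FALSE) {
  stopifnot(inherits(matrix, "supervised_matrix"), inherits(split, "stage_split"),
            inherits(spec, "model_spec"))
  sm <- select_inputs(matrix, spec$met_vars, spec$pm_lags)
  if (spec$use_wavelet) sm <- expand_wavelet_features(sm, spec$wavelet)
  fit_rows <- if (paper_norm) seq_along(sm$y) else split$training
  norm <- fit_minmax(cbind(sm$x, target = sm$y)[fit_rows, , drop = FALSE])
  xn <- apply_minmax(norm, sm$x)
  yn <- drop(apply_minmax(norm, matrix(sm$y, ncol = 1,
                                       dimnames = list(NULL, "target"))))
  model <- init_model(ncol(xn), spec$n_hidden, seed = spec$config$seed,
                      hidden_act = spec$hidden_act, output_act = spec$output_act)
  result <- train(model, xn[split$training, , drop = FALSE], yn[split$training],
                  spec$config,
                  val_rows = xn[split$verification, , drop = FALSE],
                  val_targets = yn[split$verification])
  out <- list(spec = spec, norm = norm, model = result$model, result = result,
              split = split, input_cols = colnames(xn), paper_norm = paper_norm)
  class(out) <- "fitted_forecaster"
  out
}

#' @export
print.fitted_forecaster <- function(x, ...) {
  cat("fitted_forecaster ", x$spec$id, ": ", length(x$input_cols), ":",
      x$spec$n_hidden, ":1 (", x$spec$hidden_act, "-", x$spec$output_act,
      "), trainer '", x$spec$config$algorithm, "', ",
      x$result$epochs, " epochs\n", sep = "")
  invisible(x)
}

#' Predict next-day PM2.5 concentrations
#'
#' Applies the stored input selection, wavelet expansion and normalization,
#' runs the forward pass, and de-normalizes the output back to ug/m3.
#'
#' @param fitted A `fitted_forecaster`.
#' @param matrix A `supervised_matrix` carrying the spec's input variables.
#' @return Numeric vector of predictions (ug/m3), one per row.
#' @export
predict_next_day <- function(fitted, matrix) {
  stopifnot(inherits(fitted, "fitted_forecaster"),
            inherits(matrix, "supervised_matrix"))
  sm <- select_inputs(matrix, fitted$spec$met_vars, fitted$spec$pm_lags)
  if (fitted$spec$use_wavelet) {
    sm <- expand_wavelet_features(sm, fitted$spec$wavelet)
  }
  xn <- apply_minmax(fitted$norm, sm$x[, fitted$input_cols, drop = FALSE])
  qn <- forward(fitted$model, xn)
  span <- fitted$norm$s_max["target"] - fitted$norm$s_min["target"]
  drop(qn * span + fitted$norm$s_min["target"])
}

# --- serialization --------------------------------------------------------

#' Serialize a network or forecaster to JSON
#'
#' `save_mlp()`/`load_mlp()` round-trip an `mlp_model` bit-exactly through
#' a documented JSON layout (dimensions, activations, flattened
#' parameters).  `save_forecaster()` writes a bundle directory with
#' `model.json`, `normparams.json` and `spec.yaml`.
#'
#' @param model An `mlp_model`.
#' @param path Output file path.
#' @return `load_mlp()` returns the restored `mlp_model`; the save
#'   functions return their path(s) invisibly.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  payload <- list(
    n_inputs = ncol(model$W1), n_hidden = nrow(model$W1),
    hidden_act = model$hidden_act, output_act = model$output_act,
    # parameters as shortest round-trip decimal strings: reload is bit-exact
    theta = sprintf("%.17g", pack_params(model))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  proto <- mlp_model(matrix(0, p$n_hidden, p$n_inputs), numeric(p$n_hidden),
                     numeric(p$n_hidden), 0, p$hidden_act, p$output_act)
  unpack_params(as.numeric(p$theta), proto)
}

#' @rdname save_mlp
#' @param fitted A `fitted_forecaster`.
#' @param dir Bundle directory (created if needed).
#' @export
save_forecaster <- function(fitted, dir) {
  stopifnot(inherits(fitted, "fitted_forecaster"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_mlp(fitted$model, file.path(dir, "model.json"))
  jsonlite::write_json(list(s_min = as.list(fitted$norm$s_min),
                            s_max = as.list(fitted$norm$s_max)),
                       file.path(dir, "normparams.json"),
                       digits = NA, auto_unbox = TRUE)
  sp <- fitted$spec
  yaml::write_yaml(list(
    id = sp$id, met_vars = as.list(sp$met_vars), pm_lags = as.list(sp$pm_lags),
    use_wavelet = sp$use_wavelet,
    wavelet = list(wavelet = sp$wavelet$wavelet, level = sp$wavelet$level,
                   mode = sp$wavelet$mode, causal = sp$wavelet$causal),
    n_hidden = sp$n_hidden, hidden_act = sp$hidden_act,
    output_act = sp$output_act,
    algorithm = sp$config$algorithm, seed = sp$config$seed,
    input_cols = as.list(fitted$input_cols), paper_norm = fitted$paper_norm
  ), file.path(dir, "spec.yaml"))
  invisible(dir)
}
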