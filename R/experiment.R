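# End-to-end experiment orchestration behind the command-line interface:
# load or simulate data, split, fit the requested models, write staged
# reports, serialized forecasters, and a reproducibility log.

#' Run an end-to-end forecasting experiment
#'
#' `config` is a list (or path to a YAML file) with:
#' \describe{
#'   \item{data}{either `list(csv = "path")` or
#'     `list(synthetic = "path/to/config.yaml")` /
#'     `list(synthetic = list(...))` with [synthetic_config()] fields
#'     (exactly one source).}
#'   \item{split}{optional: `fractions` (default 0.8/0.1/0.1) or
#'     `boundaries` (two dates).}
#'   \item{models}{character vector of preset ids (default `"ANN1"`) or a
#'     list of [model_spec()] objects.}
#'   \item{algorithm, max_epochs, n_hidden}{optional overrides applied to
#'     preset models.}
#'   \item{pm_lags, met_vars, horizon}{optional supervised-design
#'     overrides.}
#'   \item{seed}{base seed (default 1).}
#'   \item{outdir}{output directory.}
#' }
#'
#' Writes `report.csv` / `report.json` (staged metrics), one bundle
#' directory and `predictions.csv` per model, `config.yaml`, and `run.log`
#' with the seed, config hash and package version.
#'
#' @param config List or YAML path.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list with `report`, `fitted`, `outdir`.
#' @export
run_experiment <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  # --- data ---------------------------------------------------------------
  src <- config$data
  if (is.null(src) || sum(!vapply(src[c("csv", "synthetic")], is.null,
                                  logical(1))) != 1L) {
    stop("config$data must name exactly one source: csv or synthetic",
         call. = FALSE)
  }
  series <- if (!is.null(src$csv)) {
    read_daily_csv(src$csv, missing_policy = config$missing_policy %||% "error")
  } else {
    sc <- if (is.character(src$synthetic)) {
      read_synthetic_config(src$synthetic)
    } else {
      do.call(synthetic_config, src$synthetic %||% list())
    }
    sc$seed <- config$seed %||% sc$seed
    generate_daily_series(sc)$series
  }

  sm <- build_supervised(series,
                         pm_lags = config$pm_lags %||% c(0, 1, 2),
                         met_vars = config$met_vars %||% met_schema(),
                         horizon = config$horizon %||% 1)
  split <- if (!is.null(config$split$boundaries)) {
    chronological_split(sm, boundaries = as.Date(unlist(config$split$boundaries)))
  } else {
    chronological_split(sm, fractions = unlist(config$split$fractions %||%
                                                 c(0.8, 0.1, 0.1)))
  }

  # --- models -------------------------------------------------------------
  model_ids <- config$models %||% "ANN1"
  fitted <- list()
  reports <- list()
  for (i in seq_along(model_ids)) {
    m <- model_ids[[i]]
    spec <- if (inherits(m, "model_spec")) {
      m
    } else {
      cfg <- train_config(algorithm = config$algorithm %||% "lm",
                          max_epochs = config$max_epochs %||% 100,
                          seed = seed + i)
      sp <- preset_model_spec(m, config = cfg)
      if (!is.null(config$n_hidden)) sp$n_hidden <- as.integer(config$n_hidden)
      sp
    }
    fit <- fit_forecaster(sm, split, spec)
    fitted[[spec$id]] <- fit
    reports[[spec$id]] <- stage_report(fit, sm, split)
    bundle <- file.path(outdir, paste0("model_", spec$id))
    save_forecaster(fit, bundle)
    pred <- predict_next_day(fit, sm)
    utils::write.csv(
      data.frame(date = format(sm$target_dates, "%Y-%m-%d"),
                 observed = sm$y, predicted = pred),
      file.path(bundle, "predictions.csv"), row.names = FALSE, quote = FALSE)
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  utils::write.csv(format_report(report), file.path(outdir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       digits = NA, dataframe = "rows")

  # --- reproducibility log ------------------------------------------------
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_path)
  log_lines <- c(
    paste0("wannpm version: ", as.character(utils::packageVersion("wannpm"))),
    paste0("seed: ", seed),
    paste0("config hash: ", unname(tools::md5sum(cfg_path))),
    paste0("rows: ", length(sm$y)),
    paste0("models: ", paste(names(fitted), collapse = ", "))
  )
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(list(report = report, fitted = fitted, outdir = outdir))
}

# Reports print with 4 decimals; computation stays at full precision.
format_report <- function(report) {
  num <- vapply(report, is.numeric, logical(1)) & names(report) != "n"
  report[num] <- lapply(report[num], function(x) sprintf("%.4f", x))
  report
}

serializable_config <- function(config) {
  rapply(config, function(x) {
    if (inherits(x, "Date")) format(x) else x
  }, how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
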