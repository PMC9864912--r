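# Daily multivariate series: PM2.5 plus fourteen meteorological elements.

#' Variable schema of a daily series
#'
#' The fifteen observed variables: `pm25` (daily mean PM2.5, ug/m3) and the
#' fourteen meteorological elements -- precipitation `p` (mm), extreme wind
#' velocity `ewv` (m/s), mean atmospheric pressure `map` (hPa), mean wind
#' velocity `mwv` (m/s), mean air temperature `mat` (degC), mean water-vapour
#' pressure `mwp` (hPa), mean relative humidity `mrh` (%), sunshine hours
#' `sh` (h), minimum pressure `minap` (hPa), minimum temperature `minat`
#' (degC), maximum pressure `maxap` (hPa), maximum temperature `maxat`
#' (degC), maximum wind velocity `maxwv` (m/s), minimum relative humidity
#' `minrh` (%).
#'
#' @return Character vector of variable names (pm25 first).
#' @export
series_schema <- function() {
  c("pm25", met_schema())
}

#' @rdname series_schema
#' @export
met_schema <- function() {
  c("p", "ewv", "map", "mwv", "mat", "mwp", "mrh", "sh",
    "minap", "minat", "maxap", "maxat", "maxwv", "minrh")
}

#' Construct a daily series
#'
#' A `daily_series` is a data frame with a `date` column of strictly
#' consecutive calendar days and one numeric column per schema variable,
#' with no missing values.
#'
#' @param df Data frame with a `date` column (Date or ISO-8601 character)
#'   and the columns of [series_schema()].
#' @return A `daily_series` object.
#' @export
daily_series <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"date" %in% names(df)) stop("column 'date' is required", call. = FALSE)
  missing_cols <- setdiff(series_schema(), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing schema columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, c("date", series_schema())]
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates", call. = FALSE)
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$date)) {
    dup <- df$date[duplicated(df$date)][1L]
    stop("duplicate date: ", format(dup), call. = FALSE)
  }
  if (nrow(df) > 1L && any(diff(df$date) != 1L)) {
    i <- which(diff(df$date) != 1L)[1L]
    stop("calendar gap between ", format(df$date[i]), " and ",
         format(df$date[i + 1L]), call. = FALSE)
  }
  for (v in series_schema()) {
    if (!is.numeric(df[[v]])) stop("column '", v, "' is not numeric", call. = FALSE)
    if (anyNA(df[[v]])) stop("missing values in column '", v, "'", call. = FALSE)
  }
  class(df) <- c("daily_series", "data.frame")
  df
}

#' Read a daily PM2.5 + meteorology CSV
#'
#' Expects a header `date, pm25, p, ewv, map, mwv, mat, mwp, mrh, sh, minap,
#' minat, maxap, maxat, maxwv, minrh` with ISO-8601 dates.  Rows are sorted
#' by date; duplicate dates are an error.  Calendar gaps and missing cells
#' follow `missing_policy`: `"error"` (default) fails, `"ffill"` inserts the
#' missing days and carries the last observation forward.
#'
#' @param path Path to the CSV file.
#' @param missing_policy Either `"error"` or `"ffill"`.
#' @return A [daily_series()].
#' @export
read_daily_csv <- function(path, missing_policy = c("error", "ffill")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         strip.white = TRUE)
  missing_cols <- setdiff(c("date", series_schema()), names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date in row ", which(is.na(dates))[1L], call. = FALSE)
  }
  ord <- order(dates)
  raw <- raw[ord, , drop = FALSE]
  dates <- dates[ord]
  if (anyDuplicated(dates)) {
    stop("duplicate date: ", format(dates[duplicated(dates)][1L]), call. = FALSE)
  }
  vals <- list()
  for (v in series_schema()) {
    cell <- raw[[v]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !(is.na(cell) | cell == ""))
    if (length(bad) > 0L) {
      stop("non-numeric value '", cell[bad[1L]], "' in column '", v,
           "', row ", bad[1L], call. = FALSE)
    }
    vals[[v]] <- num
  }
  df <- data.frame(date = dates, vals)

  has_gap <- nrow(df) > 1L && any(diff(df$date) != 1L)
  has_na <- anyNA(df[series_schema()])
  if ((has_gap || has_na) && missing_policy == "error") {
    if (has_gap) {
      i <- which(diff(df$date) != 1L)[1L]
      stop("calendar gap between ", format(df$date[i]), " and ",
           format(df$date[i + 1L]), " (missing_policy = 'error')", call. = FALSE)
    }
    na_col <- series_schema()[vapply(df[series_schema()], anyNA, logical(1))][1L]
    stop("missing value in column '", na_col, "' (missing_policy = 'error')",
         call. = FALSE)
  }
  if (has_gap) {
    full <- data.frame(date = seq(min(df$date), max(df$date), by = "day"))
    df <- merge(full, df, by = "date", all.x = TRUE, sort = TRUE)
  }
  if (anyNA(df[series_schema()])) {
    for (v in series_schema()) df[[v]] <- ffill(df[[v]])
    if (anyNA(df[series_schema()])) {
      stop("leading missing values cannot be forward-filled", call. = FALSE)
    }
  }
  daily_series(df)
}

ffill <- function(x) {
  idx <- cumsum(!is.na(x))
  x[idx > 0] <- x[!is.na(x)][idx[idx > 0]]
  x
}

#' Build a lagged supervised design for next-day forecasting
#'
#' Each row holds the predictors of a reference day `t` (meteorological
#' variables at `t` and PM2.5 at the requested lags) and the PM2.5 target
#' `horizon` days ahead.  Row count is `n - max(pm_lags) - horizon`.
#'
#' @param series A [daily_series()].
#' @param pm_lags Integer lags of PM2.5 to include as predictors
#'   (0 = same day `t`, 1 = `t-1`, ...).  May be empty.
#' @param met_vars Meteorological variables (subset of [met_schema()]) taken
#'   at the reference day.  May be empty.
#' @param horizon Forecast horizon in days (>= 1).
#' @return A `supervised_matrix`: list with predictor matrix `x` (named
#'   columns, met vars first then `pm25_t`, `pm25_tm1`, ...), target vector
#'   `y` (ug/m3), `ref_dates`, `target_dates`, and the building parameters.
#' @export
build_supervised <- function(series, pm_lags = c(0, 1, 2),
                             met_vars = met_schema(), horizon = 1) {
  stopifnot(inherits(series, "daily_series"))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  pm_lags <- sort(unique(as.integer(pm_lags)))
  if (length(pm_lags) > 0L && any(pm_lags < 0L)) {
    stop("pm_lags must be non-negative", call. = FALSE)
  }
  bad <- setdiff(met_vars, met_schema())
  if (length(bad) > 0L) {
    stop("unknown met_vars: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(met_vars) == 0L && length(pm_lags) == 0L) {
    stop("at least one predictor is required", call. = FALSE)
  }
  n <- nrow(series)
  max_lag <- if (length(pm_lags) > 0L) max(pm_lags) else 0L
  n_rows <- n - max_lag - horizon
  if (n_rows < 1L) {
    stop("series too short: ", n, " days leave no usable rows for max lag ",
         max_lag, " and horizon ", horizon, call. = FALSE)
  }
  t_idx <- seq(max_lag + 1L, n - horizon)   # reference days
  cols <- list()
  for (v in met_vars) cols[[v]] <- series[[v]][t_idx]
  for (k in pm_lags) {
    nm <- if (k == 0L) "pm25_t" else paste0("pm25_tm", k)
    cols[[nm]] <- series$pm25[t_idx - k]
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  out <- list(
    x = x,
    y = series$pm25[t_idx + horizon],
    ref_dates = series$date[t_idx],
    target_dates = series$date[t_idx + horizon],
    pm_lags = pm_lags,
    met_vars = met_vars,
    horizon = horizon
  )
  class(out) <- "supervised_matrix"
  out
}

#' @export
print.supervised_matrix <- function(x, ...) {
  cat("supervised_matrix:", nrow(x$x), "rows x", ncol(x$x), "predictors,",
      "horizon", x$horizon, "day(s)\n")
  cat("columns:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}

#' Chronological training / verification / predicting split
#'
#' Splits the rows of a supervised design into three contiguous stages,
#' either by fractions (default 80/10/10: training size rounded down, ties
#' in the remainder going to verification) or by explicit boundary dates on
#' the target dates (end of training, end of verification).
#'
#' @param matrix A `supervised_matrix` from [build_supervised()].
#' @param fractions Numeric length 3 summing to 1.
#' @param boundaries Optional `Date` (or ISO string) vector of length 2;
#'   takes precedence over `fractions` when supplied.
#' @return A `stage_split`: list of integer row-index vectors `training`,
#'   `verification`, `predicting` (disjoint, ordered, exhaustive).
#' @export
chronological_split <- function(matrix, fractions = c(0.8, 0.1, 0.1),
                                boundaries = NULL) {
  stopifnot(inherits(matrix, "supervised_matrix"))
  n <- length(matrix$y)
  if (!is.null(boundaries)) {
    boundaries <- as.Date(boundaries)
    if (length(boundaries) != 2L || anyNA(boundaries)) {
      stop("boundaries must be two valid dates", call. = FALSE)
    }
    td <- matrix$target_dates
    if (boundaries[1] < min(td) || boundaries[2] >= max(td) ||
        boundaries[1] >= boundaries[2]) {
      stop("boundaries must lie strictly inside the target date range and be ordered",
           call. = FALSE)
    }
    tr <- which(td <= boundaries[1])
    ve <- which(td > boundaries[1] & td <= boundaries[2])
    pr <- which(td > boundaries[2])
  } else {
    if (length(fractions) != 3L || any(fractions <= 0) ||
        abs(sum(fractions) - 1) > 1e-8) {
      stop("fractions must be three positive numbers summing to 1", call. = FALSE)
    }
    n_tr <- floor(fractions[1] * n)
    rem <- n - n_tr
    n_ve <- ceiling(rem * fractions[2] / (fractions[2] + fractions[3]))
    n_pr <- rem - n_ve
    tr <- seq_len(n_tr)
    ve <- seq(n_tr + 1L, length.out = n_ve)
    pr <- seq(n_tr + n_ve + 1L, length.out = n_pr)
  }
  if (length(tr) == 0L || length(ve) == 0L || length(pr) == 0L) {
    stop("every stage must be non-empty", call. = FALSE)
  }
  out <- list(training = as.integer(tr), verification = as.integer(ve),
              predicting = as.integer(pr))
  class(out) <- "stage_split"
  out
}

#' @export
print.stage_split <- function(x, ...) {
  cat("stage_split: training ", length(x$training),
      " / verification ", length(x$verification),
      " / predicting ", length(x$predicting), " rows\n", sep = "")
  invisible(x)
}

#' Min--max normalization
#'
#' `fit_minmax()` records the per-column minimum and maximum of its input;
#' `apply_minmax()` maps each column to `(s - s_min)/(s_max - s_min)` (so
#' `s_min` becomes 0 and `s_max` becomes 1) and `invert_minmax()` undoes it.
#'
#' @param rows Numeric matrix (or vector treated as one column named
#'   `"target"`) with named columns.
#' @return `fit_minmax()`: a `norm_params` object with vectors `s_min`,
#'   `s_max`.  The other two return a matrix/vector shaped like their input.
#' @export
fit_minmax <- function(rows) {
  rows <- as_named_matrix(rows)
  s_min <- apply(rows, 2, min)
  s_max <- apply(rows, 2, max)
  degenerate <- which(s_max - s_min <= 0)
  if (length(degenerate) > 0L) {
    stop("constant column cannot be normalized: ",
         paste(colnames(rows)[degenerate], collapse = ", "), call. = FALSE)
  }
  out <- list(s_min = s_min, s_max = s_max)
  class(out) <- "norm_params"
  out
}

as_named_matrix <- function(rows) {
  if (is.null(dim(rows))) {
    rows <- matrix(rows, ncol = 1, dimnames = list(NULL, "target"))
  }
  rows <- as.matrix(rows)
  if (is.null(colnames(rows))) {
    stop("rows must have column names", call. = FALSE)
  }
  rows
}

#' @rdname fit_minmax
#' @param params A `norm_params` object.
#' @export
apply_minmax <- function(params, rows) {
  vec <- is.null(dim(rows))
  rows <- as_named_matrix(rows)
  out <- minmax_transform(params, rows, invert = FALSE)
  if (vec) drop(out) else out
}

#' @rdname fit_minmax
#' @export
invert_minmax <- function(params, rows) {
  vec <- is.null(dim(rows))
  rows <- as_named_matrix(rows)
  out <- minmax_transform(params, rows, invert = TRUE)
  if (vec) drop(out) else out
}

minmax_transform <- function(params, rows, invert) {
  stopifnot(inherits(params, "norm_params"))
  unknown <- setdiff(colnames(rows), names(params$s_min))
  if (length(unknown) > 0L) {
    stop("no normalization parameters for column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lo <- params$s_min[colnames(rows)]
  span <- params$s_max[colnames(rows)] - lo
  if (invert) {
    sweep(sweep(rows, 2, span, "*"), 2, lo, "+")
  } else {
    sweep(sweep(rows, 2, lo, "-"), 2, span, "/")
  }
}

#' Annual descriptive statistics of one variable
#'
#' Per-calendar-year mean, minimum and maximum, the multi-year mean
#' (unweighted mean of the annual means) and the endpoint percent change
#' `(mean_first - mean_last) / mean_first * 100` (positive = decrease).
#'
#' @param series A [daily_series()].
#' @param variable Variable name (default `"pm25"`).
#' @return List with `table` (year, mean, min, max, n_days, complete),
#'   `multi_year_mean`, and `percent_change`.
#' @export
annual_statistics <- function(series, variable = "pm25") {
  stopifnot(inherits(series, "daily_series"))
  if (!variable %in% series_schema()) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  year <- as.integer(format(series$date, "%Y"))
  x <- series[[variable]]
  years <- sort(unique(year))
  tab <- data.frame(
    year = years,
    mean = vapply(years, function(yy) mean(x[year == yy]), numeric(1)),
    min = vapply(years, function(yy) min(x[year == yy]), numeric(1)),
    max = vapply(years, function(yy) max(x[year == yy]), numeric(1)),
    n_days = vapply(years, function(yy) sum(year == yy), numeric(1))
  )
  days_in_year <- ifelse(is_leap(years), 366L, 365L)
  tab$complete <- tab$n_days == days_in_year
  if (!any(tab$complete)) {
    warning("series covers no complete calendar year; annual means are partial")
  }
  mm <- mean(tab$mean)
  pc <- (tab$mean[1L] - tab$mean[nrow(tab)]) / tab$mean[1L] * 100
  list(table = tab, multi_year_mean = mm, percent_change = pc)
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Matched calendar windows used for the 2019 vs 2020 lockdown comparison
#'
#' Window I: 1--26 January (pre-lockdown), window II: 27 January -- 30 April
#' (lockdown), window III: 1 May -- 31 July (post-lockdown).
#'
#' @return Named list of `c(start, end)` month-day strings.
#' @export
lockdown_windows <- function() {
  list(I = c("01-01", "01-26"), II = c("01-27", "04-30"), III = c("05-01", "07-31"))
}

#' Compare matched calendar windows between two years
#'
#' For each window the mean of `variable` is computed in `year_a` and
#' `year_b`; `delta = mean_a - mean_b` and
#' `percent = delta / mean_a * 100`, so a positive value means the later
#' year is lower.
#'
#' @param series A [daily_series()].
#' @param variable Variable name.
#' @param windows Named list of `c("mm-dd", "mm-dd")` windows
#'   (default [lockdown_windows()]).
#' @param year_a,year_b The reference (earlier) and comparison year.
#' @return Data frame: window, start, end, mean_a, mean_b, delta, percent.
#' @export
compare_periods <- function(series, variable = "pm25",
                            windows = lockdown_windows(),
                            year_a, year_b) {
  stopifnot(inherits(series, "daily_series"))
  if (!variable %in% series_schema()) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (length(windows) == 0L) stop("windows must be non-empty", call. = FALSE)
  nm <- names(windows)
  if (is.null(nm)) nm <- as.character(seq_along(windows))
  win_mean <- function(year, w) {
    from <- as.Date(paste0(year, "-", w[1]))
    to <- as.Date(paste0(year, "-", w[2]))
    sel <- series$date >= from & series$date <= to
    if (!any(sel)) {
      stop("window ", w[1], "..", w[2], " has no data in year ", year,
           call. = FALSE)
    }
    mean(series[[variable]][sel])
  }
  mean_a <- vapply(windows, function(w) win_mean(year_a, w), numeric(1))
  mean_b <- vapply(windows, function(w) win_mean(year_b, w), numeric(1))
  delta <- mean_a - mean_b
  data.frame(
    window = nm,
    start = vapply(windows, `[`, character(1), 1L),
    end = vapply(windows, `[`, character(1), 2L),
    mean_a = mean_a,
    mean_b = mean_b,
    delta = delta,
    percent = delta / mean_a * 100,
    row.names = NULL
  )
}
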