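# Synthetic daily PM2.5 + meteorology generator.  The target follows an
# AR(1) process driven linearly by minimum temperature (negative coupling)
# and maximum pressure (positive coupling) over a seasonal meteorological
# background, with optional short-period structure and truncation at zero.
# All other schema variables are documented noisy transforms so that every
# pipeline component can run on a complete series.

#' Configure the synthetic generator
#'
#' Defaults emulate a seven-year mid-latitude coastal record: seasonal
#' temperature with ~10.5 degC amplitude, pressure anti-correlated with
#' temperature, and a PM2.5 process
#' `pm25(t+1) = c0 + phi * pm25(t) + beta_T * minat(t) +
#'  beta_P * (maxap(t) - ap_ref) [+ short-period term] + noise`,
#' truncated at zero.  `beta_T < 0` and `beta_P > 0` reproduce the sign
#' structure exploited by the top-correlated predictors (colder and
#' higher-pressure days carry more PM2.5).
#'
#' @param n_days Series length (>= 64; default 2556, about seven years).
#' @param start First date (ISO-8601).
#' @param temp_amplitude Seasonal amplitude of mean temperature (degC).
#' @param temp_phase Day-of-year of the temperature minimum.
#' @param phi AR(1) coefficient of PM2.5 (|phi| < 1).
#' @param beta_T Coupling to minimum temperature (ug/m3 per degC; < 0).
#' @param beta_P Coupling to maximum pressure (ug/m3 per hPa; > 0).
#' @param ap_ref Reference pressure subtracted from maxap (hPa).
#' @param c0 Baseline term (ug/m3).
#' @param noise_sd Innovation standard deviation (ug/m3; >= 0).
#' @param multiscale If `TRUE`, adds a short-period (weekly) oscillation to
#'   PM2.5 -- the regime in which wavelet detail components carry signal.
#' @param multiscale_amplitude,multiscale_period Amplitude (ug/m3) and
#'   period (days) of that oscillation.
#' @param seed Integer seed.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_days = 2556, start = "2014-01-01",
                             temp_amplitude = 10.5, temp_phase = 28,
                             phi = 0.6, beta_T = -0.5, beta_P = 0.4,
                             ap_ref = 1018, c0 = 23, noise_sd = 6,
                             multiscale = FALSE, multiscale_amplitude = 8,
                             multiscale_period = 7, seed = 1) {
  n_days <- as.integer(n_days)
  if (n_days < 64L) stop("n_days must be >= 64", call. = FALSE)
  if (abs(phi) >= 1) stop("phi must satisfy |phi| < 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (multiscale_period <= 1) stop("multiscale_period must be > 1", call. = FALSE)
  out <- as.list(environment())
  out$start <- as.Date(start)
  if (is.na(out$start)) stop("invalid start date", call. = FALSE)
  class(out) <- "synthetic_config"
  out
}

#' Read a synthetic-generator config from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(synthetic_config)))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(synthetic_config, vals)
}

#' Generate a synthetic daily series with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `series` (a [daily_series()]) and `truth`: the
#'   configuration, the conditional-mean next-day PM2.5 (`target_mean`,
#'   aligned to `target_dates`), and the count of zero-truncated days.
#' @export
generate_daily_series <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_days
  dates <- seq(config$start, by = "day", length.out = n)
  doy <- as.numeric(format(dates, "%j"))
  seas <- -cos(2 * pi * (doy - config$temp_phase) / 365.25)

  mat <- 17 + config$temp_amplitude * seas + stats::rnorm(n, 0, 1.5)
  minat <- mat - 3.5 - abs(stats::rnorm(n, 0, 1))
  maxat <- mat + 4.5 + abs(stats::rnorm(n, 0, 1))
  map <- 1015.5 - 0.85 * (mat - 17) + stats::rnorm(n, 0, 2)
  maxap <- map + 3 + abs(stats::rnorm(n, 0, 0.5))
  minap <- map - 3 - abs(stats::rnorm(n, 0, 0.5))
  mwp <- pmax(1, 17 + 0.9 * (mat - 17) + stats::rnorm(n, 0, 1.5))
  mrh <- pmin(100, pmax(30, 75 + stats::rnorm(n, 0, 8)))
  minrh <- pmax(5, mrh - 15 - abs(stats::rnorm(n, 0, 5)))
  mwv <- 2.5 + abs(stats::rnorm(n, 0, 1))
  maxwv <- mwv + 2 + abs(stats::rnorm(n, 0, 1))
  ewv <- maxwv + 1.5 + abs(stats::rnorm(n, 0, 1))
  wet <- stats::rbinom(n, 1, 0.35)
  p <- wet * stats::rgamma(n, shape = 0.6, scale = 12)
  sh <- pmax(0, 7 - 4 * wet + stats::rnorm(n, 0, 2.5))

  short <- if (config$multiscale) {
    config$multiscale_amplitude * sin(2 * pi * seq_len(n) / config$multiscale_period)
  } else {
    numeric(n)
  }
  eps <- stats::rnorm(n, 0, config$noise_sd)
  pm25 <- numeric(n)
  cond_mean <- rep(NA_real_, n)   # cond_mean[t+1] = E[pm25(t+1) | day t]
  pm25[1] <- max(0, (config$c0 + config$beta_T * minat[1] +
                       config$beta_P * (maxap[1] - config$ap_ref)) /
                   (1 - config$phi))
  truncated <- 0L
  for (t in seq_len(n - 1L)) {
    mu_t <- config$c0 + config$phi * pm25[t] + config$beta_T * minat[t] +
      config$beta_P * (maxap[t] - config$ap_ref) + short[t + 1L]
    cond_mean[t + 1L] <- max(0, mu_t)
    val <- mu_t + eps[t + 1L]
    if (val < 0) truncated <- truncated + 1L
    pm25[t + 1L] <- max(0, val)
  }

  series <- daily_series(data.frame(
    date = dates, pm25 = pm25, p = p, ewv = ewv, map = map, mwv = mwv,
    mat = mat, mwp = mwp, mrh = mrh, sh = sh, minap = minap, minat = minat,
    maxap = maxap, maxat = maxat, maxwv = maxwv, minrh = minrh
  ))
  list(series = series,
       truth = list(config = config,
                    target_dates = dates[-1L],
                    target_mean = cond_mean[-1L],
                    truncated_days = truncated))
}

#' Noise-free next-day targets of a generated series
#'
#' Returns, for each requested date, the conditional mean of PM2.5 on that
#' date given the previous day's realized state (the generative mean with
#' the innovation set to zero, truncated at zero).
#'
#' @param generated Result of [generate_daily_series()].
#' @param dates Dates within the generated target range.
#' @return Numeric vector of noise-free values, one per date.
#' @export
oracle_targets <- function(generated, dates) {
  dates <- as.Date(dates)
  idx <- match(dates, generated$truth$target_dates)
  if (anyNA(idx)) {
    stop("date out of the generated target range: ",
         format(dates[is.na(idx)][1L]), call. = FALSE)
  }
  generated$truth$target_mean[idx]
}

#' Write a generated series to the standard CSV schema
#'
#' @param series A [daily_series()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_daily_csv <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  df <- as.data.frame(series)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
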