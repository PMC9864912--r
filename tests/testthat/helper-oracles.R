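# Independent oracles and small fixture builders used across the suite.

# Brute-force periodized filter bank: explicit scalar loops over circular
# convolution, downsampling, upsampling -- independent of the package's
# vectorized implementation.
naive_dwt_per <- function(x, dec_lo, dec_hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  nc <- n / 2
  a <- numeric(nc)
  d <- numeric(nc)
  for (k in seq_len(nc)) {
    for (j in seq_along(dec_lo)) {
      idx <- ((2 * (k - 1) + (j - 1)) %% n) + 1
      a[k] <- a[k] + dec_lo[j] * x[idx]
      d[k] <- d[k] + dec_hi[j] * x[idx]
    }
  }
  list(a = a, d = d)
}

naive_idwt_per <- function(a, d, rec_lo, rec_hi) {
  nc <- length(a)
  n <- 2 * nc
  x <- numeric(n)
  rl <- rev(rec_lo)
  rh <- rev(rec_hi)
  for (k in seq_len(nc)) {
    for (j in seq_along(rl)) {
      idx <- ((2 * (k - 1) + (j - 1)) %% n) + 1
      x[idx] <- x[idx] + a[k] * rl[j] + d[k] * rh[j]
    }
  }
  x
}

# Level-2 component reconstruction through the naive filter bank.
naive_components_level2 <- function(x, wavelet) {
  f <- wannpm:::.wavelet_registry[[wavelet]]
  l1 <- naive_dwt_per(x, f$dec_lo, f$dec_hi)
  l2 <- naive_dwt_per(l1$a, f$dec_lo, f$dec_hi)
  z1 <- numeric(length(l1$d))
  z2 <- numeric(length(l2$d))
  ca2 <- naive_idwt_per(naive_idwt_per(l2$a, z2, f$rec_lo, f$rec_hi),
                        z1, f$rec_lo, f$rec_hi)
  cd2 <- naive_idwt_per(naive_idwt_per(numeric(length(l2$a)), l2$d,
                                       f$rec_lo, f$rec_hi),
                        z1, f$rec_lo, f$rec_hi)
  cd1 <- naive_idwt_per(numeric(length(l1$a)), l1$d, f$rec_lo, f$rec_hi)
  cbind(CA2 = ca2, CD2 = cd2, CD1 = cd1)
}

# Central finite-difference gradient of a scalar function.
num_gradient <- function(fn, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + eps
    tm[i] <- tm[i] - eps
    (fn(tp) - fn(tm)) / (2 * eps)
  }, numeric(1))
}

# Daily series with a prescribed pm25 vector; meteorological columns are
# simple distinct non-constant fillers.
make_series <- function(pm25, start = "2014-01-01") {
  n <- length(pm25)
  tt <- seq_len(n)
  df <- data.frame(date = seq(as.Date(start), by = "day", length.out = n),
                   pm25 = pm25)
  for (i in seq_along(met_schema())) {
    df[[met_schema()[i]]] <- sin(tt / (3 + i)) + i + tt * 1e-4
  }
  daily_series(df)
}

# Series whose value is constant within each calendar year.
make_annual_series <- function(annual_means, first_year = 2014) {
  years <- first_year + seq_along(annual_means) - 1
  dates <- seq(as.Date(paste0(first_year, "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  pm <- annual_means[match(as.integer(format(dates, "%Y")), years)]
  df <- as.data.frame(make_series(pm))
  df$date <- dates
  daily_series(df)
}

# Small exactly-linear supervised problem on named columns.
make_linear_problem <- function(n = 60, seed = 1, noise = 0) {
  set.seed(seed)
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(0.4, -0.3, 0.2)) + 0.1 + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# Two vectors with (numerically) exact correlation r.
make_correlated_pair <- function(r, n = 200, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(stats::lm(e ~ x))
  xs <- scale(x)[, 1]
  es <- scale(e)[, 1]
  y <- r * xs + sqrt(1 - r^2) * es
  list(x = xs, y = y)
}
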