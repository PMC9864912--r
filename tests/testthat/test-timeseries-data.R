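test_that("read_daily_csv loads well-formed files and enforces structure", {
  s <- make_series(c(10, 20, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_csv(s, path)
  loaded <- read_daily_csv(path)
  expect_s3_class(loaded, "daily_series")
  expect_equal(nrow(loaded), 3L)
  expect_equal(loaded$pm25, c(10, 20, 30))

  # duplicate date
  df <- as.data.frame(s)
  df$date <- as.Date(c("2014-01-01", "2014-01-01", "2014-01-02"))
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_daily_csv(path), "duplicate date")

  # calendar gap, policy = error vs ffill
  df <- as.data.frame(make_series(c(10, 20, 30)))
  df <- df[c(1, 3), ]
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_daily_csv(path), "gap")
  filled <- read_daily_csv(path, missing_policy = "ffill")
  expect_equal(nrow(filled), 3L)
  expect_equal(filled$pm25, c(10, 10, 30))

  # non-numeric cell names row and column
  df <- as.data.frame(make_series(c(10, 20, 30)))
  df$date <- format(df$date)
  df$mat[2] <- "oops"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_daily_csv(path), "'mat'.*row 2")
})

test_that("build_supervised shapes, names and aligns lagged rows", {
  s <- make_series(seq(10, 100, by = 10))   # n = 10
  sm <- build_supervised(s, pm_lags = c(0, 1, 2), met_vars = met_schema(),
                         horizon = 1)
  expect_equal(dim(sm$x), c(7L, 17L))
  expect_equal(colnames(sm$x)[15:17], c("pm25_t", "pm25_tm1", "pm25_tm2"))
  # row 1: reference day t = 3
  expect_equal(unname(sm$x[1, c("pm25_t", "pm25_tm1", "pm25_tm2")]),
               c(30, 20, 10))
  expect_equal(sm$y[1], 40)
  expect_equal(sm$target_dates, sm$ref_dates + 1)

  one <- build_supervised(s, pm_lags = 0, met_vars = character(0))
  expect_equal(ncol(one$x), 1L)
  expect_equal(colnames(one$x), "pm25_t")

  expect_error(build_supervised(make_series(c(1, 2, 3)), pm_lags = c(0, 1, 2)),
               "too short")
})

test_that("supervised rows never leak: every target date is after its reference", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    lags <- sort(sample(0:4, sample(1:3, 1)))
    h <- sample(1:3, 1)
    if (n - max(lags) - h < 1) next
    sm <- build_supervised(make_series(rnorm(n, 50, 10)), pm_lags = lags,
                           met_vars = "mat", horizon = h)
    expect_true(all(sm$target_dates > sm$ref_dates))
    expect_equal(length(sm$y), n - max(lags) - h)
  }
})

test_that("chronological_split honours fractions and boundary dates", {
  s <- make_series(rnorm(103, 50, 5))
  sm <- build_supervised(s)             # 100 rows
  sp <- chronological_split(sm)
  expect_equal(lengths(sp), c(training = 80L, verification = 10L, predicting = 10L))

  b <- chronological_split(sm, boundaries = c(sm$target_dates[70], sm$target_dates[85]))
  expect_equal(length(b$training), 70L)
  expect_equal(length(b$verification), 15L)
  expect_equal(max(sm$target_dates[b$verification]), sm$target_dates[85])

  # boundary outside the range / producing an empty stage
  expect_error(chronological_split(sm, boundaries = c(max(sm$target_dates),
                                                      max(sm$target_dates) + 5)),
               "inside")
})

test_that("splits are disjoint, ordered and exhaustive for random sizes", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(12:400, 1)
    f1 <- runif(1, 0.5, 0.9)
    f2 <- runif(1, 0.05, (1 - f1) - 0.05)
    sm <- build_supervised(make_series(rnorm(n + 3, 40, 5)))
    sp <- chronological_split(sm, fractions = c(f1, f2, 1 - f1 - f2))
    all_idx <- c(sp$training, sp$verification, sp$predicting)
    expect_equal(sort(all_idx), seq_along(sm$y))
    expect_equal(anyDuplicated(all_idx), 0L)
    expect_true(max(sp$training) < min(sp$verification))
    expect_true(max(sp$verification) < min(sp$predicting))
  }
})

test_that("min-max normalization maps endpoints and inverts exactly", {
  x <- cbind(a = c(2, 4, 6), b = c(-1, 0, 3))
  np <- fit_minmax(x)
  n <- apply_minmax(np, x)
  expect_equal(unname(n[1, "a"]), 0)        # s_min -> 0
  expect_equal(unname(n[3, "a"]), 1)        # s_max -> 1
  expect_equal(unname(apply_minmax(np, cbind(a = 4, b = 1))[1, ]), c(0.5, 0.5))

  set.seed(9)
  r <- matrix(rnorm(60, 10, 40), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  np2 <- fit_minmax(r)
  expect_lt(max(abs(invert_minmax(np2, apply_minmax(np2, r)) - r)), 1e-12)

  bad <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(fit_minmax(bad), "constant column.*a")
})

test_that("annual statistics aggregate yearly means and endpoint change", {
  means <- c(52.33, 53.67, 44.67, 38.25, 34.17, 35.17, 31.75)
  s <- make_annual_series(means)
  st <- annual_statistics(s, "pm25")
  expect_equal(st$table$mean, means)
  expect_equal(st$multi_year_mean, mean(means))
  expect_equal(st$percent_change, (means[1] - means[7]) / means[1] * 100)
  expect_true(all(st$table$complete))
  # internal consistency: multi-year mean is the mean of the table column
  expect_equal(st$multi_year_mean, mean(st$table$mean))

  const <- annual_statistics(make_annual_series(rep(40, 3)), "pm25")
  expect_equal(const$percent_change, 0)
  expect_error(annual_statistics(s, "nope"), "unknown variable")
})

test_that("compare_periods computes matched-window deltas with the decrease convention", {
  # two years; window values constant by period
  dates <- seq(as.Date("2019-01-01"), as.Date("2020-12-31"), by = "day")
  md <- format(dates, "%m-%d")
  yr <- format(dates, "%Y")
  val <- numeric(length(dates))
  lv <- list(`2019` = c(I = 53.12, II = 43.11, III = 29.58, rest = 40),
             `2020` = c(I = 52.62, II = 32.41, III = 31.99, rest = 35))
  win <- function(md, a, b) md >= a & md <= b
  for (y in c("2019", "2020")) {
    sel <- yr == y
    val[sel & win(md, "01-01", "01-26")] <- lv[[y]]["I"]
    val[sel & win(md, "01-27", "04-30")] <- lv[[y]]["II"]
    val[sel & win(md, "05-01", "07-31")] <- lv[[y]]["III"]
    val[sel & md > "07-31"] <- lv[[y]]["rest"]
  }
  df <- as.data.frame(make_series(val))
  df$date <- dates
  s <- daily_series(df)

  rep <- compare_periods(s, "pm25", year_a = 2019, year_b = 2020)
  expect_equal(rep$delta, c(0.5, 10.7, -2.41), tolerance = 1e-10)
  expect_equal(rep$percent[2], 10.7 / 43.11 * 100)
  expect_lt(rep$delta[3], 0)   # period III increased in 2020

  same <- compare_periods(s, "pm25", year_a = 2019, year_b = 2019)
  expect_equal(same$delta, rep(0, 3))
  expect_equal(same$percent, rep(0, 3))

  expect_error(compare_periods(s, "pm25", windows = list(c("01-01", "01-31")),
                               year_a = 2019, year_b = 2025),
               "no data")
})
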