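test_that("constant series lives entirely in the approximation component", {
  wc <- wavelet_decompose(rep(5, 8), wavelet_spec("bior1.1", 2, "periodization"))
  expect_equal(colnames(wc$components), c("CA2", "CD2", "CD1"))
  expect_equal(unname(wc$components[, "CA2"]), rep(5, 8))
  expect_equal(max(abs(wc$components[, c("CD2", "CD1")])), 0)
})

test_that("components sum back to the signal for every wavelet and both modes", {
  set.seed(21)
  # full registry on a few lengths (even, odd, not a power of two)
  for (w in list_wavelets()) {
    for (mode in c("periodization", "symmetric")) {
      for (n in c(16, 33, 100)) {
        x <- cumsum(rnorm(n))
        wc <- wavelet_decompose(x, wavelet_spec(w, 2, mode))
        expect_lt(max(abs(rowSums(wc$components) - x)), 1e-8)
      }
    }
  }
  # 200 random series, lengths 16..4096, random wavelet/mode/level
  for (i in 1:200) {
    n <- sample(16:4096, 1)
    w <- sample(list_wavelets(), 1)
    mode <- sample(c("periodization", "symmetric"), 1)
    lev <- sample(1:min(3, floor(log2(n))), 1)
    x <- rnorm(n, 50, 20)
    wc <- wavelet_decompose(x, wavelet_spec(w, lev, mode))
    expect_equal(ncol(wc$components), lev + 1L)
    expect_equal(nrow(wc$components), n)
    expect_lt(max(abs(rowSums(wc$components) - x)), 1e-8)
  }
})

test_that("level-2 components match an independent brute-force filter bank", {
  # unit impulse, Haar (= bior1.1)
  x <- c(0, 0, 0, 1, 0, 0, 0, 0)
  wc <- wavelet_decompose(x, wavelet_spec("bior1.1", 2, "periodization"))
  oracle <- naive_components_level2(x, "bior1.1")
  expect_equal(unname(wc$components), unname(oracle), tolerance = 1e-12)

  # random inputs, all registry wavelets, n = 16
  set.seed(5)
  x <- rnorm(16)
  for (w in list_wavelets()) {
    wc <- wavelet_decompose(x, wavelet_spec(w, 2, "periodization"))
    expect_equal(unname(wc$components), unname(naive_components_level2(x, w)),
                 tolerance = 1e-10)
  }
})

test_that("orthogonal wavelets under periodization give uncorrelated components", {
  set.seed(31)
  x <- cumsum(rnorm(256)) + 10 * sin(seq_len(256) / 9)
  ortho <- c("bior1.1", "db2", "db4", "db6", "sym3", "sym5", "coif2", "coif4")
  for (w in ortho) {
    r <- component_correlation(wavelet_decompose(x, wavelet_spec(w, 2, "periodization")))
    expect_lt(max(abs(r[upper.tri(r)])), 1e-10)
  }
})

test_that("component_correlation handles diagonals and degenerate components", {
  set.seed(6)
  wc <- wavelet_decompose(rnorm(64), wavelet_spec("db3", 2))
  r <- component_correlation(wc)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_true(all(abs(r[!is.na(r)]) <= 1 + 1e-12))

  # constant detail components are flagged NA, not zero
  r2 <- component_correlation(cbind(a = rnorm(32), b = rep(2, 32), c = rnorm(32)))
  expect_true(all(is.na(r2["b", c("a", "c")])))
  expect_error(component_correlation(cbind(a = rep(1, 8), b = rep(2, 8))),
               "constant")
})

test_that("mother-wavelet selection ranks by mean absolute component correlation", {
  set.seed(7)
  x <- rnorm(256)
  sel <- select_mother_wavelet(x, c("bior2.2", "bior1.1"))
  expect_equal(sel$best, "bior1.1")
  expect_lt(sel$table$score[1], 1e-10)
  expect_gt(sel$table$score[2], 1e-6)
  expect_true(!is.unsorted(sel$table$score))

  single <- select_mother_wavelet(x, "bior5.5")
  expect_equal(single$best, "bior5.5")

  # duplicate candidates tie; the first occurrence wins (stable order)
  dup <- select_mother_wavelet(x, c("db2", "db2", "bior2.2"))
  expect_equal(dup$table$wavelet[1:2], c("db2", "db2"))
  expect_error(select_mother_wavelet(x, character(0)), "non-empty")
})

test_that("full 21-wavelet selection on a seeded series picks an orthogonal wavelet", {
  set.seed(8)
  x <- cumsum(rnorm(256, 0, 5)) + 40
  sel <- select_mother_wavelet(x)
  expect_equal(nrow(sel$table), 21L)
  expect_lt(sel$table$score[1], 1e-10)   # some orthogonal wavelet scores ~0
})

test_that("causal decomposition is prefix-stable and agrees at the endpoint", {
  set.seed(9)
  x <- rnorm(150, 50, 10)
  spec <- wavelet_spec("bior1.1", 2)
  c1 <- decompose_causal(x, spec, min_window = 64)
  c2 <- decompose_causal(c(x, rnorm(10, 50, 10)), spec, min_window = 64)
  expect_equal(c1$components, c2$components[seq_along(x), ])

  whole <- wavelet_decompose(x, spec)
  expect_equal(c1$components[length(x), ], whole$components[length(x), ])

  cc <- decompose_causal(rep(3, 100), spec, min_window = 64)
  ww <- wavelet_decompose(rep(3, 100), spec)
  expect_equal(cc$components, ww$components)

  expect_error(decompose_causal(rnorm(32), spec, min_window = 64), "shorter")
  expect_error(decompose_causal(rnorm(100), spec, min_window = 2), "min_window")
})

test_that("invalid wavelet requests fail with informative errors", {
  expect_error(wavelet_decompose(rnorm(2), wavelet_spec("db2", 2)), "too short")
  expect_error(wavelet_spec("db99"), "db2")            # error lists the registry
  expect_error(wavelet_decompose(c(1, NA, 3, 4), wavelet_spec("db2", 1)),
               "finite")
  expect_length(list_wavelets(), 21L)
})
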