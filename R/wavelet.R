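# Discrete wavelet decomposition by the Mallat pyramid: cascaded two-channel
# analysis on the approximation branch, component reconstruction by the
# adjoint synthesis bank.  Boundary handling is either circular
# ("periodization", which keeps the transform an exact change of basis) or
# whole-point symmetric reflection ("symmetric", slightly redundant
# coefficients, still perfectly invertible).

#' Specify a wavelet decomposition
#'
#' @param wavelet Mother wavelet name (see [list_wavelets()]).
#' @param level Decomposition depth `m` (>= 1, default 2: components CA2,
#'   CD2, CD1).
#' @param mode Boundary extension: `"periodization"` (default; makes the
#'   additive reconstruction exact to machine precision and orthogonal
#'   wavelets exactly orthogonal) or `"symmetric"`.
#' @param causal If `TRUE`, [wavelet_decompose()] uses the leakage-safe
#'   prefix recursion of [decompose_causal()].
#' @param min_window Minimum prefix length for causal decomposition.
#' @return A `wavelet_spec` object.
#' @export
wavelet_spec <- function(wavelet = "bior1.1", level = 2,
                         mode = c("periodization", "symmetric"),
                         causal = FALSE, min_window = 64) {
  mode <- match.arg(mode)
  wavelet_filters(wavelet)  # validates the name
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  out <- list(wavelet = wavelet, level = level, mode = mode,
              causal = isTRUE(causal), min_window = as.integer(min_window))
  class(out) <- "wavelet_spec"
  out
}

# --- single-level analysis/synthesis steps --------------------------------

# Periodized analysis: a[k] = sum_j h[j] x[(j + 2(k-1) - 1) mod N + 1].
# Odd-length inputs are padded by repeating the last sample (linear in x).
dwt_step_per <- function(x, filt) {
  n0 <- length(x)
  if (n0 %% 2L == 1L) x <- c(x, x[n0])
  n <- length(x)
  L <- length(filt$dec_lo)
  nc <- n %/% 2L
  idx <- outer(2L * (seq_len(nc) - 1L), seq_len(L) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], nrow = nc)
  list(a = drop(xm %*% filt$dec_lo), d = drop(xm %*% filt$dec_hi), len = n0)
}

# Adjoint synthesis of the periodized analysis (exact inverse).
idwt_step_per <- function(a, d, filt, out_len) {
  nc <- length(a)
  n <- 2L * nc
  L <- length(filt$rec_lo)
  rl <- rev(filt$rec_lo)
  rh <- rev(filt$rec_hi)
  x <- numeric(n)
  base <- 2L * (seq_len(nc) - 1L)
  for (j in seq_len(L)) {
    pos <- (base + j - 1L) %% n + 1L
    contrib <- a * rl[j] + d * rh[j]
    # positions can repeat when L > N: accumulate, do not overwrite
    x[pos] <- x[pos] + contrib
  }
  x[seq_len(out_len)]
}

# Symmetric (whole-point reflection) extension, folding as often as needed.
sym_extend <- function(x, e) {
  n <- length(x)
  idx <- seq(-e, n + e - 1L) %% (2L * n)
  idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx)
  x[idx + 1L]
}

dwt_step_sym <- function(x, filt) {
  n <- length(x)
  L <- length(filt$dec_lo)
  ext <- sym_extend(x, L - 1L)
  nv <- n + L - 1L                       # valid-convolution length
  idx <- outer(seq_len(nv) - 1L, seq_len(L), "+")
  em <- matrix(ext[idx], nrow = nv)
  ylo <- drop(em %*% rev(filt$dec_lo))
  yhi <- drop(em %*% rev(filt$dec_hi))
  keep <- seq(2L, nv, by = 2L)
  list(a = ylo[keep], d = yhi[keep], len = n)
}

idwt_step_sym <- function(a, d, filt, out_len) {
  nc <- length(a)
  L <- length(filt$rec_lo)
  up_a <- numeric(2L * nc); up_a[seq(1L, 2L * nc, by = 2L)] <- a
  up_d <- numeric(2L * nc); up_d[seq(1L, 2L * nc, by = 2L)] <- d
  full <- numeric(2L * nc + L - 1L)
  for (j in seq_len(L)) {
    sl <- seq(j, length.out = 2L * nc)
    full[sl] <- full[sl] + filt$rec_lo[j] * up_a + filt$rec_hi[j] * up_d
  }
  out <- full[seq(L - 1L, length.out = 2L * nc - L + 2L)]
  out[seq_len(out_len)]
}

# --- multi-level transform ------------------------------------------------

wavedec <- function(x, wavelet, level, mode) {
  filt <- wavelet_filters(wavelet)
  step <- if (mode == "periodization") dwt_step_per else dwt_step_sym
  details <- vector("list", level)
  lens <- integer(level)
  cur <- x
  for (i in seq_len(level)) {
    s <- step(cur, filt)
    details[[i]] <- s$d
    lens[i] <- s$len
    cur <- s$a
  }
  list(approx = cur, details = details, lens = lens,
       wavelet = wavelet, mode = mode)
}

waverec <- function(tree) {
  filt <- wavelet_filters(tree$wavelet)
  step <- if (tree$mode == "periodization") idwt_step_per else idwt_step_sym
  cur <- tree$approx
  for (i in rev(seq_along(tree$details))) {
    cur <- step(cur, tree$details[[i]], filt, tree$lens[i])
  }
  cur
}

# Reconstruct one branch with all other coefficient vectors zeroed.
reconstruct_branch <- function(tree, which) {
  z <- tree
  if (which == "approx") {
    z$details <- lapply(z$details, function(d) numeric(length(d)))
  } else {
    k <- as.integer(which)
    z$approx <- numeric(length(z$approx))
    z$details <- lapply(seq_along(z$details), function(i) {
      if (i == k) z$details[[i]] else numeric(length(z$details[[i]]))
    })
  }
  waverec(z)
}

#' Decompose a series into full-length wavelet components
#'
#' Performs an `m`-level discrete wavelet decomposition (only the
#' approximation branch is re-decomposed) and reconstructs each coefficient
#' branch back to the length of the input, yielding the approximation
#' component `CAm` and detail components `CDm ... CD1` whose element-wise
#' sum restores the original series.
#'
#' @param series Finite numeric vector of length >= `2^level`.
#' @param spec A [wavelet_spec()].
#' @return A `wavelet_components` object: list with `components` (named
#'   matrix, columns `CAm`, `CDm`, ..., `CD1`) and `spec`.
#' @export
wavelet_decompose <- function(series, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (isTRUE(spec$causal)) {
    return(decompose_causal(series, spec, spec$min_window))
  }
  series <- as.numeric(series)
  check_decomposable(series, spec)
  tree <- wavedec(series, spec$wavelet, spec$level, spec$mode)
  m <- spec$level
  comp <- matrix(0, nrow = length(series), ncol = m + 1L)
  colnames(comp) <- c(paste0("CA", m), paste0("CD", rev(seq_len(m))))
  comp[, 1L] <- reconstruct_branch(tree, "approx")
  for (i in seq_len(m)) {
    comp[, paste0("CD", i)] <- reconstruct_branch(tree, i)
  }
  out <- list(components = comp, spec = spec)
  class(out) <- "wavelet_components"
  out
}

check_decomposable <- function(series, spec) {
  if (any(!is.finite(series))) stop("series must be finite", call. = FALSE)
  if (length(series) < 2^spec$level) {
    stop("series of length ", length(series),
         " is too short for a level-", spec$level, " decomposition",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.wavelet_components <- function(x, ...) {
  cat("wavelet_components:", x$spec$wavelet, "level", x$spec$level,
      paste0("(", x$spec$mode, if (isTRUE(x$spec$causal)) ", causal", "), "),
      nrow(x$components), "observations x", ncol(x$components), "components\n")
  invisible(x)
}

#' Leakage-safe causal wavelet decomposition
#'
#' Whole-series decomposition lets boundary effects carry information about
#' future observations into earlier component values.  The causal variant
#' emits, at each index `t >= min_window`, the final row of the
#' decomposition of the prefix `series[1..t]`; indices before `min_window`
#' take the first-window decomposition.  Appending future observations
#' never changes values already emitted.
#'
#' @param series Finite numeric vector.
#' @param spec A [wavelet_spec()].
#' @param min_window Shortest prefix decomposed (>= `2^level`).
#' @return A `wavelet_components` object.
#' @export
decompose_causal <- function(series, spec = wavelet_spec(),
                             min_window = 64) {
  stopifnot(inherits(spec, "wavelet_spec"))
  series <- as.numeric(series)
  min_window <- as.integer(min_window)
  if (min_window < 2^spec$level) {
    stop("min_window must be >= 2^level", call. = FALSE)
  }
  if (length(series) < min_window) {
    stop("series shorter than min_window (", min_window, ")", call. = FALSE)
  }
  base_spec <- spec
  base_spec$causal <- FALSE
  n <- length(series)
  first <- wavelet_decompose(series[seq_len(min_window)], base_spec)
  comp <- matrix(0, nrow = n, ncol = ncol(first$components),
                 dimnames = list(NULL, colnames(first$components)))
  comp[seq_len(min_window), ] <- first$components
  if (n > min_window) {
    for (t in seq(min_window + 1L, n)) {
      ct <- wavelet_decompose(series[seq_len(t)], base_spec)
      comp[t, ] <- ct$components[t, ]
    }
  }
  out <- list(components = comp, spec = spec)
  class(out) <- "wavelet_components"
  out
}

#' Pairwise correlation of wavelet components
#'
#' Linear correlation coefficients between all reconstructed components.
#' Components with zero variance are undefined (`NA` row/column) and are
#' excluded from selection scores.
#'
#' @param components A `wavelet_components` object (or plain matrix).
#' @return Symmetric correlation matrix with unit diagonal; `NA` for
#'   constant components.
#' @export
component_correlation <- function(components) {
  comp <- if (inherits(components, "wavelet_components")) {
    components$components
  } else {
    as.matrix(components)
  }
  if (ncol(comp) < 2L) stop("need at least two components", call. = FALSE)
  sds <- apply(comp, 2, stats::sd)
  ok <- sds > 0
  if (!any(ok)) stop("all components are constant", call. = FALSE)
  r <- matrix(NA_real_, ncol(comp), ncol(comp),
              dimnames = list(colnames(comp), colnames(comp)))
  r[ok, ok] <- stats::cor(comp[, ok, drop = FALSE])
  diag(r)[ok] <- 1
  r
}

#' Select a mother wavelet by minimal inter-component correlation
#'
#' Decomposes every series with every candidate and scores each candidate
#' by the mean absolute off-diagonal component correlation (undefined
#' correlations from constant components are excluded).  The wavelet whose
#' components are most nearly uncorrelated wins; ties keep candidate-list
#' order.
#'
#' @param series_list A numeric vector or list of numeric vectors.
#' @param candidates Character vector of wavelet names (default: the full
#'   21-wavelet registry) or list of [wavelet_spec()] objects.
#' @param level,mode Used when `candidates` are names.
#' @return List with `table` (wavelet, score, ranked ascending) and `best`.
#' @export
select_mother_wavelet <- function(series_list, candidates = list_wavelets(),
                                  level = 2, mode = "periodization") {
  if (is.numeric(series_list)) series_list <- list(series_list)
  if (length(candidates) == 0L) stop("candidates must be non-empty", call. = FALSE)
  specs <- lapply(candidates, function(cand) {
    if (inherits(cand, "wavelet_spec")) cand
    else wavelet_spec(cand, level = level, mode = mode)
  })
  score_one <- function(spec) {
    rs <- unlist(lapply(series_list, function(x) {
      r <- component_correlation(wavelet_decompose(x, spec))
      abs(r[upper.tri(r)])
    }))
    rs <- rs[!is.na(rs)]
    if (length(rs) == 0L) return(NA_real_)
    mean(rs)
  }
  scores <- vapply(specs, score_one, numeric(1))
  wnames <- vapply(specs, function(s) s$wavelet, character(1))
  ord <- order(scores)                      # stable: ties keep list order
  tab <- data.frame(wavelet = wnames[ord], score = scores[ord],
                    row.names = NULL)
  list(table = tab, best = tab$wavelet[1L])
}
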