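# Performance criteria: MAE, RMSE and the linear correlation coefficient R
# between observed and predicted concentrations, plus derived R^2 and a
# relative error, reported per chronological stage.

#' Forecast performance metrics
#'
#' `MAE = (1/U) sum |A_k - C_k|`, `RMSE = sqrt((1/U) sum (A_k - C_k)^2)`,
#' `R` the Pearson correlation between observed `A` and predicted `C`,
#' `R2 = R^2`, and `RE = RMSE / mean(A)` (relative error; the RMSE scaled
#' by the mean observed level -- a documented in-package convention).
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return Named list: `MAE`, `RMSE`, `R`, `R2`, `RE`.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted differ in length", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least two pairs", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("R is undefined for a constant observed or predicted series",
         call. = FALSE)
  }
  err <- observed - predicted
  r <- stats::cor(observed, predicted)
  list(MAE = mean(abs(err)),
       RMSE = sqrt(mean(err^2)),
       R = r,
       R2 = r^2,
       RE = sqrt(mean(err^2)) / mean(observed))
}

#' Staged evaluation report for a fitted forecaster
#'
#' Predicts every stage of the split and computes [compute_metrics()] on
#' the de-normalized (ug/m3) scale, one row per stage.
#'
#' @param fitted A `fitted_forecaster`.
#' @param matrix The `supervised_matrix` the split indexes into.
#' @param split A `stage_split` (defaults to the one stored in `fitted`).
#' @return Data frame: model, stage, MAE, RMSE, R, R2, RE, n.
#' @export
stage_report <- function(fitted, matrix, split = fitted$split) {
  stopifnot(inherits(fitted, "fitted_forecaster"),
            inherits(matrix, "supervised_matrix"), inherits(split, "stage_split"))
  stages <- c("training", "verification", "predicting")
  if (any(vapply(split[stages], length, integer(1)) == 0L)) {
    stop("every stage must be non-empty", call. = FALSE)
  }
  pred_all <- predict_next_day(fitted, matrix)
  rows <- lapply(stages, function(st) {
    idx <- split[[st]]
    m <- compute_metrics(matrix$y[idx], pred_all[idx])
    data.frame(model = fitted$spec$id, stage = st, MAE = m$MAE, RMSE = m$RMSE,
               R = m$R, R2 = m$R2, RE = m$RE, n = length(idx))
  })
  do.call(rbind, rows)
}

#' Staged comparison table for several fitted forecasters
#'
#' @param fitted_list List of `fitted_forecaster` objects.
#' @param matrix,split As in [stage_report()].
#' @return Row-bound stage reports (models x stages).
#' @export
performance_table <- function(fitted_list, matrix, split) {
  do.call(rbind, lapply(fitted_list, stage_report, matrix = matrix, split = split))
}
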