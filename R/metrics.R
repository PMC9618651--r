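#' Normalized root mean square error
#'
#' RMSE divided by the range (max - min) of the ground truth of the
#' evaluated dataset; dimensionless, reported as a fraction.
#'
#' @param y Ground-truth vector (length >= 2, non-constant).
#' @param yhat Predictions, same length.
#' @return Scalar NRMSE (fraction).
#' @export
#' @examples
#' nrmse(c(0, 1, 2), c(0, 1, 3))  # sqrt(1/3) / 2
nrmse <- function(y, yhat) {
  if (length(y) != length(yhat)) abort_shape("`y` and `yhat` must have equal lengths")
  if (length(y) < 2L) abort_shape("NRMSE needs at least two points")
  rng <- max(y) - min(y)
  if (rng <= 0) abort_config("ground truth is constant; NRMSE range is degenerate")
  sqrt(mean((y - yhat)^2)) / rng
}

#' Mean absolute error
#'
#' @param y,yhat Numeric vectors of equal length.
#' @return Scalar MAE in target units.
#' @export
#' @examples
#' mae(c(1, 2), c(1.1, 1.8))  # 0.15
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) abort_shape("`y` and `yhat` must have equal lengths")
  if (length(y) < 1L) abort_shape("empty input to mae")
  mean(abs(y - yhat))
}

#' Per-output accuracy metrics from prediction matrices
#'
#' Computes NRMSE, MAE and MAPE per output channel on the physical target
#' scale. The truth range used by NRMSE is recorded per channel for
#' transparency.
#'
#' @param y,yhat Matrices `(n, outputs)` of truth and predictions.
#' @param channels Output channel names.
#' @param label Dataset label stored in the report.
#' @param epsilon MAPE denominator floor.
#' @return A `metrics_report` tibble, one row per output channel.
#' @export
metrics_from_predictions <- function(y, yhat, channels = colnames(y),
                                     label = "test", epsilon = 1e-3) {
  y <- as.matrix(y)
  yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) abort_shape("`y` and `yhat` must share a shape")
  channels <- channels %||% paste0("y", seq_len(ncol(y)))
  out <- purrr::map_dfr(seq_len(ncol(y)), function(k) {
    tibble::tibble(
      channel = channels[k],
      nrmse = nrmse(y[, k], yhat[, k]),
      mae = mae(y[, k], yhat[, k]),
      mape = mape_loss(y[, k], yhat[, k], epsilon = epsilon),
      n = nrow(y),
      truth_range = max(y[, k]) - min(y[, k]),
      dataset = label
    )
  })
  class(out) <- c("metrics_report", class(out))
  out
}

#' Evaluate a model on a windowed dataset
#'
#' One-step-ahead predictions over every data point, with NRMSE, MAE and
#' MAPE per output channel on the physical target scale (targets are never
#' normalized by the pipeline). If both the fitted model and the dataset
#' carry a normalization-statistics hash, they must match; evaluating
#' against data prepared with different statistics is a provenance error.
#'
#' @param model A `motion_model` or `motion_model_fit`.
#' @param dataset A `windowed_dataset` normalized with training statistics.
#' @param label Dataset label stored in the report.
#' @param epsilon MAPE denominator floor.
#' @return A `metrics_report` tibble.
#' @export
evaluate <- function(model, dataset, label = "test", epsilon = 1e-3) {
  fit_hash <- if (inherits(model, "motion_model_fit")) model$stats_hash else NULL
  data_hash <- attr(dataset, "stats_hash")
  if (!is.null(fit_hash) && !is.null(data_hash) && !identical(fit_hash, data_hash)) {
    abort_provenance(
      "normalization statistics mismatch between the fitted model and this dataset"
    )
  }
  if (inherits(model, "motion_model_fit")) model <- model$model
  yhat <- predict(model, dataset)
  metrics_from_predictions(dataset$y, yhat, channels = colnames(dataset$y),
                           label = label, epsilon = epsilon)
}
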