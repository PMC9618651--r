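#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted model
#'
#' One row per epoch and loss series (training / validation, total and per
#' output), in long format.
#'
#' @param x A `motion_model_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `series`, `loss`, `lr`.
#' @exportS3Method generics::tidy
tidy.motion_model_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(
      cols = -c("epoch", "lr"),
      names_to = "series", values_to = "loss"
    ) |>
    dplyr::select("epoch", "series", "loss", "lr")
}

#' One-row summary of a fitted model
#'
#' @param x A `motion_model_fit`.
#' @param ... Unused.
#' @return A one-row tibble: topology, attention flag, window, parameter
#'   count, epochs run, best epoch, best validation loss, final learning
#'   rate.
#' @exportS3Method generics::glance
glance.motion_model_fit <- function(x, ...) {
  tibble::tibble(
    topology = x$model$spec$topology,
    attention = x$model$spec$attention,
    bidirectional = x$model$spec$bidirectional,
    window = x$model$spec$window,
    n_parameters = count_parameters(x$model),
    epochs = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_lr = utils::tail(x$history$lr, 1)
  )
}

#' Plot training and validation loss curves
#'
#' @param object A `motion_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.motion_model_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$series %in% c("loss", "val_loss"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "MAPE loss (fraction)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A `spectrum_report`.
#' @param boundary Optional boundary frequency drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum_report <- function(object, boundary = 6, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power") +
    ggplot2::theme_minimal()
  if (!is.null(boundary)) {
    p <- p + ggplot2::geom_vline(xintercept = boundary, linetype = "dashed")
  }
  p
}

#' Plot mean attention weights per timestep
#'
#' Averages each attention layer's weights over the evaluated data points
#' to show which timesteps of the input window the model attends to.
#'
#' @param model A `motion_model` or `motion_model_fit` with attention.
#' @param dataset A `windowed_dataset`.
#' @param max_points Number of data points sampled for the summary.
#' @return A ggplot object.
#' @export
plot_attention <- function(model, dataset, max_points = 512) {
  if (inherits(model, "motion_model_fit")) model <- model$model
  if (!model$spec$attention) abort_config("model has no attention layers")
  n <- n_points(dataset)
  idx <- seq_len(min(n, max_points))
  pr <- predict(model, subset_windowed(dataset, idx), attention = TRUE)
  df <- dplyr::bind_rows(
    tibble::tibble(layer = "rescale (layer 1)",
                   timestep = seq_len(ncol(pr$alpha1)),
                   alpha = colMeans(pr$alpha1)),
    tibble::tibble(layer = "context (layer 2)",
                   timestep = seq_len(ncol(pr$alpha2)),
                   alpha = colMeans(pr$alpha2))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$timestep, .data$alpha, colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "timestep in window", y = "mean attention weight", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predictions against ground truth
#'
#' @param truth,pred Numeric vectors (one target channel).
#' @param fs Sampling frequency used for the time axis.
#' @param channel Label for the y axis.
#' @return A ggplot object.
#' @export
plot_predictions <- function(truth, pred, fs = 100, channel = "resultant acceleration") {
  df <- tibble::tibble(
    time_s = rep((seq_along(truth) - 1) / fs, 2),
    value = c(truth, pred),
    series = rep(c("truth", "prediction"), each = length(truth))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = channel, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
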