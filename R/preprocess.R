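#' Resultant acceleration from triaxial accelerometer components
#'
#' Element-wise Euclidean norm of three co-indexed acceleration series.
#'
#' @param ax,ay,az Numeric vectors of equal length, m/s^2.
#' @return Non-negative numeric vector, m/s^2.
#' @export
#' @examples
#' resultant_acceleration(3, 4, 0)  # 5
resultant_acceleration <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ax) != length(az)) {
    abort_shape("`ax`, `ay` and `az` must have equal lengths")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Centred moving-average smoothing
#'
#' A k-point centred moving average used to clean the target channels
#' before training. At the edges the window shrinks symmetrically (at row
#' i it spans `i - m .. i + m` with `m = min((k-1)/2, i-1, n-i)`) so the
#' output has the same length as the input. Smoothing is offline target
#' clean-up, so the non-causal centred alignment is acceptable.
#'
#' @param x Numeric series, length >= `k`.
#' @param k Odd window length, default 5.
#' @return Smoothed series, same length as `x`.
#' @export
#' @examples
#' moving_average_smooth(c(0, 0, 1, 0, 0), k = 5)
moving_average_smooth <- function(x, k = 5) {
  if (!is_count(k) || k < 1 || k %% 2 == 0) {
    abort_config("`k` must be a positive odd integer")
  }
  n <- length(x)
  if (n < k) abort_shape("series shorter than the smoothing window")
  h <- (k - 1) / 2
  i <- seq_len(n)
  m <- pmin(h, i - 1, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + m + 1] - cs[i - m]) / (2 * m + 1)
}

#' Fit and apply per-channel z-score normalization
#'
#' `fit_normalization()` computes per-input-channel mean and standard
#' deviation; by contract these statistics are computed on training data
#' only and then applied unchanged to validation and test data.
#'
#' @param data Data frame (or matrix) containing the channels.
#' @param channels Channels to normalize; defaults to the input channels
#'   present in `data`.
#' @return `fit_normalization()` returns a `normalization_stats` tibble
#'   (`channel`, `mean`, `sd`); `apply_normalization()` returns `data` with
#'   the fitted channels transformed to `(x - mean) / sd`.
#' @export
fit_normalization <- function(data, channels = NULL) {
  df <- as.data.frame(data)
  if (nrow(df) == 0L) abort_shape("cannot fit normalization on empty data")
  channels <- channels %||% intersect(input_channel_names(), names(df))
  if (length(channels) == 0L) abort_config("no input channels found in `data`")
  mu <- vapply(df[channels], mean, 0)
  sd_ <- vapply(df[channels], stats::sd, 0)
  degenerate <- channels[!is.finite(sd_) | sd_ < 1e-12]
  if (length(degenerate)) {
    abort_config(paste0(
      "degenerate (constant) channel(s): ", paste(degenerate, collapse = ", ")
    ))
  }
  structure(
    tibble::tibble(channel = channels, mean = unname(mu), sd = unname(sd_)),
    class = c("normalization_stats", class(tibble::tibble()))
  )
}

#' @rdname fit_normalization
#' @param stats A `normalization_stats` object from [fit_normalization()].
#' @export
apply_normalization <- function(data, stats) {
  missing_ch <- setdiff(stats$channel, names(data))
  if (length(missing_ch)) {
    abort_shape(paste0("channels absent from data: ", paste(missing_ch, collapse = ", ")))
  }
  for (j in seq_len(nrow(stats))) {
    ch <- stats$channel[j]
    data[[ch]] <- (data[[ch]] - stats$mean[j]) / stats$sd[j]
  }
  data
}

new_windowed_dataset <- function(x, y, provenance, fs = NA_real_) {
  structure(
    list(x = x, y = y, provenance = provenance, fs = fs),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(
    "<windowed_dataset> %d data points x %d timesteps x %d features; %d subject(s)\n",
    d[1], d[2], d[3], length(unique(x$provenance$subject))
  ))
  invisible(x)
}

#' Number of data points in a windowed dataset
#' @param data A `windowed_dataset`.
#' @export
n_points <- function(data) dim(data$x)[1]

#' Subset a windowed dataset by data-point index
#' @param data A `windowed_dataset`.
#' @param idx Integer indices of data points to keep.
#' @return A `windowed_dataset` with the selected points.
#' @export
subset_windowed <- function(data, idx) {
  new_windowed_dataset(
    x = data$x[idx, , , drop = FALSE],
    y = data$y[idx, , drop = FALSE],
    provenance = data$provenance[idx, , drop = FALSE],
    fs = data$fs
  )
}

#' Sliding-window resampling into a 3-D training tensor
#'
#' Scans each subject's contiguous segment with a window of fixed length
#' `window`, rolling one timestep at a time: a segment of N rows yields
#' exactly `N - window` data points, where data point i holds input rows
#' `i .. i + window - 1` and its target is the target-channel value at row
#' `i + window` (the next timestep). Windows never span subject boundaries;
#' segments shorter than `window + 1` rows are skipped with a warning.
#'
#' @param data Data frame with a `subject` column, input channels and
#'   target channels (a single recording or row-bound cohort).
#' @param window Window length in timesteps (>= 1).
#' @param inputs,targets Channel names; default to the standard schema.
#' @return A `windowed_dataset`: `x` is an array shaped
#'   `(data points, timesteps, features)`, `y` a matrix of next-timestep
#'   targets, `provenance` a tibble of (subject, window start row, target
#'   row) per data point.
#' @export
sliding_window_resample <- function(data, window,
                                    inputs = NULL, targets = NULL) {
  if (!is_count(window) || window < 1) abort_config("`window` must be a positive integer")
  df <- as.data.frame(data)
  inputs <- inputs %||% intersect(input_channel_names(), names(df))
  targets <- targets %||% intersect(target_channel_names(), names(df))
  if (!length(inputs)) abort_config("no input channels found")
  if (!length(targets)) abort_config("no target channels found")
  subj <- if ("subject" %in% names(df)) as.character(df$subject) else rep("all", nrow(df))

  runs <- rle(subj)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  xs <- list(); ys <- list(); prov <- list()
  for (s in seq_along(starts)) {
    nseg <- runs$lengths[s]
    if (nseg < window + 1L) {
      warn(sprintf(
        "segment for subject '%s' has %d rows (< window + 1 = %d); skipped",
        runs$values[s], nseg, window + 1L
      ))
      next
    }
    seg_rows <- starts[s]:ends[s]
    Xseg <- as.matrix(df[seg_rows, inputs, drop = FALSE])
    Yseg <- as.matrix(df[seg_rows, targets, drop = FALSE])
    npt <- nseg - window
    xa <- array(0, dim = c(npt, window, length(inputs)))
    for (t in seq_len(window)) {
      xa[, t, ] <- Xseg[t:(t + npt - 1L), ]
    }
    xs[[length(xs) + 1L]] <- xa
    ys[[length(ys) + 1L]] <- Yseg[(window + 1L):nseg, , drop = FALSE]
    prov[[length(prov) + 1L]] <- tibble::tibble(
      subject = runs$values[s],
      window_start = seg_rows[seq_len(npt)],
      target_row = seg_rows[(window + 1L):nseg]
    )
  }
  if (!length(xs)) abort_shape("no segment is long enough to window")

  ntot <- sum(vapply(xs, function(a) dim(a)[1], 0L))
  x <- array(0, dim = c(ntot, window, length(inputs)),
             dimnames = list(NULL, NULL, inputs))
  y <- matrix(0, ntot, length(targets), dimnames = list(NULL, targets))
  at <- 0L
  for (s in seq_along(xs)) {
    k <- dim(xs[[s]])[1]
    x[(at + 1L):(at + k), , ] <- xs[[s]]
    y[(at + 1L):(at + k), ] <- ys[[s]]
    at <- at + k
  }
  new_windowed_dataset(x, y, dplyr::bind_rows(prov))
}

#' Specify a subject-disjoint train/validation/test split
#'
#' @param test_subjects Subject labels held out entirely for testing.
#' @param validation_fraction Fraction of the remaining windowed data
#'   points used for validation, in (0, 1).
#' @param shuffle_seed Integer seed governing the shuffle.
#' @return A `split_spec` object.
#' @export
split_spec <- function(test_subjects, validation_fraction = 0.15,
                       shuffle_seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort_config("`validation_fraction` must be in (0, 1)")
  }
  structure(
    list(
      test_subjects = as.character(test_subjects),
      validation_fraction = validation_fraction,
      shuffle_seed = as.integer(shuffle_seed)
    ),
    class = "split_spec"
  )
}

#' Split windowed data points by subject
#'
#' The test set receives all data points of the held-out subjects and
#' nothing else. The remaining points are shuffled with `shuffle_seed` and
#' split at the data-point level, with `floor(validation_fraction * n)`
#' points going to validation. Asserts subject-disjointness between
#' train/validation and test on every call.
#'
#' @param data A `windowed_dataset`.
#' @param spec A [split_spec()].
#' @return List of `windowed_dataset`s: `train`, `validation`, `test`.
#' @export
split_by_subject <- function(data, spec) {
  subj <- data$provenance$subject
  unknown <- setdiff(spec$test_subjects, unique(subj))
  if (length(unknown)) {
    abort_config(paste0("unknown test subject(s): ", paste(unknown, collapse = ", ")))
  }
  is_test <- subj %in% spec$test_subjects
  rest <- which(!is_test)
  shuffled <- rest[with_seed(spec$shuffle_seed, sample.int(length(rest)))]
  n_val <- floor(spec$validation_fraction * length(rest))
  if (n_val < 1 || n_val >= length(rest)) {
    abort_config("validation split is empty or swallows all training points")
  }
  val_idx <- shuffled[seq_len(n_val)]
  train_idx <- shuffled[(n_val + 1L):length(shuffled)]
  out <- list(
    train = subset_windowed(data, train_idx),
    validation = subset_windowed(data, val_idx),
    test = subset_windowed(data, which(is_test))
  )
  assert_no_leakage(out)
  out
}

# Leakage audit: train/validation subjects must be disjoint from test.
assert_no_leakage <- function(split) {
  seen <- unique(c(split$train$provenance$subject,
                   split$validation$provenance$subject))
  held <- unique(split$test$provenance$subject)
  if (length(intersect(seen, held))) {
    abort_provenance("subject leakage: test subjects appear in train/validation")
  }
  invisible(TRUE)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and
#' backward ([signal::filtfilt()]) so the output is phase-neutral; DC is
#' preserved. The default (order 2, 6 Hz cut-off at 100 Hz sampling)
#' matches the conventional pre-filter for biomechanical gait signals.
#'
#' @param x Numeric series.
#' @param order Filter order.
#' @param cutoff Cut-off frequency, Hz; must lie below the Nyquist rate.
#' @param fs Sampling frequency, Hz.
#' @return Filtered series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, order = 2, cutoff = 6, fs = 100) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    abort_config("`cutoff` must satisfy 0 < cutoff < fs / 2")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  # odd-reflection padding absorbs the filter's start-up transient (the
  # underlying filter starts from zero state), so DC really is preserved
  p <- min(n - 1L, as.integer(ceiling(10 * fs / cutoff)))
  x_pad <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, x_pad))
  y[(p + 1):(p + n)]
}

#' Smooth the target channels of a recording
#'
#' Applies the centred moving average to the target channels only; inputs
#' are left raw by default (end-to-end learning on unfiltered inputs).
#'
#' @param data Data frame with target channels.
#' @param k Odd moving-average length.
#' @param targets Target channel names.
#' @return `data` with smoothed targets.
#' @export
smooth_targets <- function(data, k = 5, targets = NULL) {
  targets <- targets %||% intersect(target_channel_names(), names(data))
  for (ch in targets) data[[ch]] <- moving_average_smooth(data[[ch]], k = k)
  data
}

#' End-to-end preprocessing: smooth, normalize, window, split
#'
#' Runs the full data-preparation pipeline on a cohort: (1) per-subject
#' target smoothing (and optional input filtering); (2) normalization
#' statistics fitted on the rows of the non-test subjects only, applied to
#' every split; (3) sliding-window resampling within subjects; (4)
#' subject-disjoint train/validation/test split with shuffling. Windows may
#' cross activity transitions but never subject boundaries.
#'
#' @param cohort Named list of recordings (e.g. from [generate_cohort()])
#'   or a single row-bound data frame with a `subject` column.
#' @param window Window length in timesteps.
#' @param spec A [split_spec()].
#' @param target_smooth_k Moving-average length for target smoothing.
#' @param input_filter Input-filter variant: `"none"` (default, raw
#'   inputs), `"ma"` (moving average) or `"butterworth"` (zero-phase
#'   low-pass).
#' @param ma_k,cutoff Parameters of the optional input filters.
#' @return List with `train`, `validation`, `test` (`windowed_dataset`s),
#'   the fitted `stats`, and the `window` length. Each split carries a
#'   `stats_hash` attribute tying it to the fitted normalization.
#' @export
prepare_windows <- function(cohort, window, spec,
                            target_smooth_k = 5,
                            input_filter = c("none", "ma", "butterworth"),
                            ma_k = 5, cutoff = 6) {
  input_filter <- match.arg(input_filter)
  if (is.data.frame(cohort)) {
    split_subj <- split(seq_len(nrow(cohort)), cohort$subject)
    cohort <- lapply(split_subj, function(i) cohort[i, , drop = FALSE])
  }
  fs_vals <- purrr::map_dbl(cohort, function(r) {
    meta <- attr(r, "gait_meta")
    if (is.null(meta)) NA_real_ else meta$fs
  })
  fs <- if (all(is.na(fs_vals))) 100 else unique(stats::na.omit(fs_vals))[1]

  cohort <- purrr::map(cohort, function(rec) {
    rec <- smooth_targets(rec, k = target_smooth_k)
    if (input_filter == "ma") {
      for (ch in intersect(input_channel_names(), names(rec))) {
        rec[[ch]] <- moving_average_smooth(rec[[ch]], k = ma_k)
      }
    } else if (input_filter == "butterworth") {
      for (ch in intersect(input_channel_names(), names(rec))) {
        rec[[ch]] <- butterworth_lowpass(rec[[ch]], cutoff = cutoff, fs = fs)
      }
    }
    rec
  })

  all_rows <- dplyr::bind_rows(purrr::map(cohort, tibble::as_tibble))
  unknown <- setdiff(spec$test_subjects, unique(all_rows$subject))
  if (length(unknown)) {
    abort_config(paste0("unknown test subject(s): ", paste(unknown, collapse = ", ")))
  }
  train_rows <- all_rows[!(all_rows$subject %in% spec$test_subjects), , drop = FALSE]
  stats <- fit_normalization(train_rows)
  normalized <- apply_normalization(all_rows, stats)

  windowed <- sliding_window_resample(normalized, window = window)
  windowed$fs <- fs
  splits <- split_by_subject(windowed, spec)
  h <- rlang::hash(stats)
  for (nm in names(splits)) attr(splits[[nm]], "stats_hash") <- h
  c(splits, list(stats = stats, window = window, fs = fs))
}
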