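#' Generate one synthetic multi-activity sensor recording
#'
#' Simulates a single subject executing a schedule of activities at a fixed
#' sampling rate. Each input channel is the sum of up to three harmonics of
#' the active profile's fundamental frequency (with subject-specific phase
#' offsets and a per-channel DC baseline) plus Gaussian noise. Each target
#' channel is `coupling_gain` times a fixed linear combination of the three
#' input resultant-acceleration channels lagged by half the instantaneous
#' fundamental period — emulating contralateral phase opposition between
#' limbs — plus Gaussian noise and sparse outlier spikes. Activity switches
#' occur at schedule boundaries with a linear cross-fade; the oscillation
#' phase evolves continuously through transitions.
#'
#' The output is bit-identical for identical `(subject, schedule, fs, seed)`.
#'
#' @param subject A [subject_params()] object.
#' @param schedule List of stages `list(profile = activity_profile, duration = seconds)`.
#' @param fs Sampling frequency in Hz; must exceed twice the highest
#'   harmonic frequency in the schedule.
#' @param seed Integer seed governing all noise and outlier draws.
#' @param crossfade Cross-fade length at activity boundaries, seconds.
#' @param outlier_rate Per-row probability of a target outlier spike.
#' @param outlier_magnitude Spike magnitude as a multiple of the target
#'   channel's deterministic standard deviation.
#' @return A tibble of class `gait_recording` with columns `time_s`,
#'   `subject`, `activity`, 30 input channels and 2 target channels, plus a
#'   `gait_meta` attribute recording the generation parameters.
#' @export
#' @examples
#' rec <- generate_subject(subject_params("S01"), default_schedule(), seed = 1)
#' dim(rec)
generate_subject <- function(subject, schedule, fs = 100, seed = 1,
                             crossfade = 0.5, outlier_rate = 0.001,
                             outlier_magnitude = 5) {
  if (!inherits(subject, "subject_params")) {
    abort_config("`subject` must be a subject_params object")
  }
  if (!is.list(schedule) || length(schedule) == 0L) {
    abort_config("`schedule` must be a non-empty list of stages")
  }
  f0 <- vapply(schedule, function(s) s$profile$fundamental_freq, 0)
  durations <- vapply(schedule, function(s) s$duration, 0)
  if (any(durations <= 0)) abort_config("stage durations must be positive")
  if (fs <= 2 * 3 * max(f0)) {
    abort_config(sprintf(
      "fs = %g Hz would alias the highest harmonic (%.2f Hz); need fs > %g Hz",
      fs, 3 * max(f0), 6 * max(f0)
    ))
  }

  ch <- input_channel_names()
  tgt <- target_channel_names()
  n_ch <- length(ch)
  n_stage <- length(schedule)
  n_rows <- round(durations * fs)
  n <- sum(n_rows)
  bounds <- cumsum(n_rows)[-n_stage]  # first row index of each new stage - 1

  # Pre-roll long enough that every lagged target index stays in range.
  pre <- ceiling(fs / (2 * min(f0))) + 2L
  n_ext <- pre + n
  trow <- seq_len(n_ext) - pre  # 1..n are the emitted rows

  # Per-stage blending weights: linear cross-fades centred on boundaries.
  ramp <- matrix(0, n_ext, max(n_stage - 1L, 1L))
  L <- max(round(crossfade * fs), 1L)
  if (n_stage > 1L) {
    for (j in seq_len(n_stage - 1L)) {
      ramp[, j] <- pmin(pmax((trow - (bounds[j] - L / 2)) / L, 0), 1)
    }
  }
  wts <- matrix(0, n_ext, n_stage)
  for (a in seq_len(n_stage)) {
    lo <- if (a == 1L) rep(1, n_ext) else ramp[, a - 1L]
    hi <- if (a == n_stage) rep(0, n_ext) else ramp[, a]
    wts[, a] <- lo - hi
  }

  f_inst <- drop(wts %*% f0)
  phase <- 2 * pi * cumsum(f_inst) / fs

  amp_stage <- lapply(schedule, function(s) s$profile$harmonic_amplitudes)
  baselines <- channel_baselines()

  with_seed(seed, {
    x <- matrix(0, n_ext, n_ch, dimnames = list(NULL, ch))
    for (j in seq_len(n_ch)) {
      det <- rep(baselines[[j]], n_ext)
      for (k in 1:3) {
        amp_k <- drop(wts %*% vapply(amp_stage, function(a) a[j, k], 0)) *
          subject$amplitude_scale
        det <- det + amp_k * sin(k * phase + subject$phase_offsets[j])
      }
      x[, j] <- det
    }
    if (subject$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n_ext * n_ch, sd = subject$noise_sd), n_ext, n_ch)
    }

    lag <- pmin(round(fs / (2 * f_inst)), seq_len(n_ext) - 1L)
    w <- coupling_weights()
    xres <- x[, colnames(w), drop = FALSE]
    y <- matrix(0, n_ext, length(tgt), dimnames = list(NULL, tgt))
    lag_idx <- seq_len(n_ext) - lag
    for (m in seq_along(tgt)) {
      y[, m] <- subject$coupling_gain * drop(xres[lag_idx, , drop = FALSE] %*% w[m, ])
    }
    y_det_sd <- apply(y[(pre + 1):n_ext, , drop = FALSE], 2L, stats::sd)
    if (subject$noise_sd > 0) {
      y <- y + matrix(stats::rnorm(n_ext * length(tgt), sd = subject$noise_sd),
                      n_ext, length(tgt))
    }
    if (outlier_rate > 0) {
      for (m in seq_along(tgt)) {
        hit <- stats::runif(n_ext) < outlier_rate
        y[hit, m] <- y[hit, m] +
          sample(c(-1, 1), sum(hit), replace = TRUE) *
            outlier_magnitude * y_det_sd[m]
      }
    }

    keep <- (pre + 1):n_ext
    stage_id <- max.col(wts[keep, , drop = FALSE], ties.method = "first")
    out <- tibble::tibble(
      time_s = (seq_len(n) - 1) / fs,
      subject = subject$subject_id,
      activity = vapply(schedule, function(s) s$profile$name, "")[stage_id]
    )
    out <- dplyr::bind_cols(
      out,
      tibble::as_tibble(x[keep, , drop = FALSE]),
      tibble::as_tibble(y[keep, , drop = FALSE])
    )
    attr(out, "gait_meta") <- list(
      fs = fs,
      seed = seed,
      subject = subject,
      schedule = list(
        activities = vapply(schedule, function(s) s$profile$name, ""),
        fundamentals = f0,
        durations = durations
      ),
      crossfade = crossfade,
      outlier_rate = outlier_rate,
      outlier_magnitude = outlier_magnitude,
      lag = as.integer(lag[keep]),
      coupling = list(
        weights = w,
        gain = subject$coupling_gain,
        channels = colnames(w)
      )
    )
    class(out) <- c("gait_recording", class(out))
    out
  })
}

#' Generate a reproducible multi-subject synthetic cohort
#'
#' Draws per-subject parameters (amplitude scale, phase offsets, coupling
#' gain) deterministically from the cohort seed, jitters each subject's
#' stage durations to emulate self-selected pace, and generates one
#' recording per subject.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule Schedule template as in [generate_subject()]; per-subject
#'   durations are jittered by +/-10%.
#' @param fs Sampling frequency, Hz.
#' @param seed Cohort seed; subject seeds and parameters derive from it.
#' @param noise_sd Sensor noise standard deviation passed to every subject.
#' @param ... Further arguments passed to [generate_subject()].
#' @return A named list of `gait_recording` tibbles, one per subject.
#' @export
#' @examples
#' cohort <- generate_cohort(3, seed = 7)
#' names(cohort)
generate_cohort <- function(n_subjects, schedule = default_schedule(),
                            fs = 100, seed = 1, noise_sd = 0.05, ...) {
  if (!is_count(n_subjects) || n_subjects < 1) {
    abort_config("`n_subjects` must be a positive integer")
  }
  recs <- purrr::map(seq_len(n_subjects), function(i) {
    params <- draw_subject_params(seed, i, noise_sd = noise_sd)
    jitter <- with_seed(derive_seed(seed, i + 10000L),
                        stats::runif(length(schedule), 0.9, 1.1))
    sched_i <- purrr::map2(schedule, jitter, function(s, j) {
      list(profile = s$profile, duration = s$duration * j)
    })
    generate_subject(params, sched_i, fs = fs,
                     seed = derive_seed(seed, i + 20000L), ...)
  })
  names(recs) <- vapply(recs, function(r) attr(r, "gait_meta")$subject$subject_id, "")
  recs
}

#' Regress targets on the generator's own lagged input combination
#'
#' Independent check that the synthetic targets are what the generator
#' claims: each target column is regressed (no intercept) on the stated
#' coupling combination of lagged input resultant-acceleration channels.
#' With zero noise and no outliers the fit recovers the coupling gain with
#' zero residual; at default noise it quantifies how learnable the targets
#' are (R^2).
#'
#' @param recording A `gait_recording`.
#' @return A tibble with one row per target channel: estimated gain, true
#'   gain, R-squared and residual standard deviation.
#' @export
coupling_oracle <- function(recording) {
  meta <- attr(recording, "gait_meta")
  if (is.null(meta)) abort_provenance("recording carries no gait_meta attribute")
  lag <- meta$lag
  n <- nrow(recording)
  rows <- which(seq_len(n) - lag >= 1L)
  xres <- as.matrix(recording[meta$coupling$channels])
  w <- meta$coupling$weights
  purrr::map_dfr(seq_len(nrow(w)), function(m) {
    tgt <- rownames(w)[m]
    comb <- drop(xres[rows - lag[rows], , drop = FALSE] %*% w[m, ])
    y <- recording[[tgt]][rows]
    fit <- stats::lm.fit(cbind(comb = comb), y)
    res <- fit$residuals
    tibble::tibble(
      channel = tgt,
      gain_estimate = unname(fit$coefficients[1]),
      gain_true = meta$coupling$gain,
      r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
      residual_sd = stats::sd(res),
      n = length(y)
    )
  })
}

#' Predictions of the generator's coupling oracle
#'
#' Returns the deterministic part of each target (gain times the lagged
#' input combination) for rows where the lag reaches back into the
#' recording, together with the corresponding target values. Serves as a
#' perfect-model reference for evaluation tests.
#'
#' @param recording A `gait_recording`.
#' @return List with `rows`, matrix `truth` and matrix `pred`.
#' @export
coupling_oracle_predictions <- function(recording) {
  meta <- attr(recording, "gait_meta")
  if (is.null(meta)) abort_provenance("recording carries no gait_meta attribute")
  lag <- meta$lag
  n <- nrow(recording)
  rows <- which(seq_len(n) - lag >= 1L)
  xres <- as.matrix(recording[meta$coupling$channels])
  w <- meta$coupling$weights
  pred <- sapply(seq_len(nrow(w)), function(m) {
    meta$coupling$gain * drop(xres[rows - lag[rows], , drop = FALSE] %*% w[m, ])
  })
  colnames(pred) <- rownames(w)
  truth <- as.matrix(recording[rows, rownames(w)])
  list(rows = rows, truth = truth, pred = pred)
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds one row per timestep (`time_s`, `subject`, `activity`, 30
#' input channels, 2 target channels); the sidecar (`<path>.json`) holds the
#' generation parameters, seed and per-row coupling lags so a recording can
#' be reloaded with its provenance intact.
#'
#' @param recording A `gait_recording`.
#' @param path Output CSV path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `gait_recording`.
#' @export
write_recording <- function(recording, path) {
  meta <- attr(recording, "gait_meta")
  readr::write_csv(tibble::as_tibble(recording), path)
  side <- list(
    fs = meta$fs,
    seed = meta$seed,
    subject = unclass(meta$subject),
    schedule = meta$schedule,
    crossfade = meta$crossfade,
    outlier_rate = meta$outlier_rate,
    outlier_magnitude = meta$outlier_magnitude,
    lag = meta$lag,
    coupling = list(
      weights = meta$coupling$weights,
      gain = meta$coupling$gain,
      channels = meta$coupling$channels
    )
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    w <- as.matrix(side$coupling$weights)
    rownames(w) <- target_channel_names()
    colnames(w) <- side$coupling$channels
    sp <- side$subject
    attr(out, "gait_meta") <- list(
      fs = side$fs,
      seed = side$seed,
      subject = subject_params(sp$subject_id, sp$amplitude_scale,
                               sp$phase_offsets, sp$noise_sd, sp$coupling_gain),
      schedule = side$schedule,
      crossfade = side$crossfade,
      outlier_rate = side$outlier_rate,
      outlier_magnitude = side$outlier_magnitude,
      lag = as.integer(side$lag),
      coupling = list(weights = w, gain = side$coupling$gain,
                      channels = side$coupling$channels)
    )
  }
  class(out) <- c("gait_recording", class(out))
  out
}
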