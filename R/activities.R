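#' Define an activity profile for the synthetic gait generator
#'
#' An activity is a quasi-periodic oscillation regime: a cadence-scale
#' fundamental frequency plus up to three harmonics per channel. All harmonic
#' frequencies (`k * fundamental_freq`, k = 1..3) stay below 6 Hz, matching
#' the band where gait signals carry their discriminative content; this
#' bounds the admissible fundamental to `[0.5, 2]` Hz.
#'
#' Per-channel harmonic amplitudes are built deterministically from a
#' per-sensor base amplitude, an activity `intensity` multiplier and a
#' harmonic decay, with a fixed per-channel variation so channels are not
#' carbon copies of each other. An `intensity` near zero yields a "stopped"
#' profile with near-zero oscillation.
#'
#' @param name Activity label.
#' @param fundamental_freq Fundamental (cadence-scale) frequency in Hz,
#'   inside `[0.5, 2]`.
#' @param intensity Unitless multiplier on all oscillation amplitudes.
#' @param duration_range Length-2 numeric, plausible bout duration in
#'   seconds (used by cohort schedules to jitter per-subject durations).
#' @return An object of class `activity_profile`.
#' @export
#' @examples
#' activity_profile("level_walk", 1.1)
activity_profile <- function(name, fundamental_freq, intensity = 1,
                             duration_range = c(4, 8)) {
  if (!is.character(name) || length(name) != 1L) {
    abort_config("`name` must be a single string")
  }
  if (!is.numeric(fundamental_freq) || length(fundamental_freq) != 1L ||
      fundamental_freq < 0.5 || fundamental_freq > 2) {
    abort_config("`fundamental_freq` must lie in [0.5, 2] Hz so that all harmonics stay below 6 Hz")
  }
  if (intensity < 0) abort_config("`intensity` must be non-negative")
  ch <- input_channel_names()
  decay <- c(1, 0.35, 0.12)
  base <- channel_base_amplitudes()
  amp <- matrix(0, nrow = length(ch), ncol = 3L,
                dimnames = list(ch, paste0("h", 1:3)))
  for (k in 1:3) {
    varfac <- 0.8 + 0.4 * (((seq_along(ch) * 7L + k * 3L) %% 11L) / 10)
    amp[, k] <- base * intensity * decay[k] * varfac
  }
  structure(
    list(
      name = name,
      fundamental_freq = fundamental_freq,
      intensity = intensity,
      harmonic_amplitudes = amp,
      duration_range = duration_range
    ),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "<activity_profile> %s: f0 = %.2f Hz, intensity = %.2f, duration %g-%g s\n",
    x$name, x$fundamental_freq, x$intensity,
    x$duration_range[1], x$duration_range[2]
  ))
  invisible(x)
}

#' Built-in activity profiles
#'
#' Six locomotion modes (level walking, stair ascent/descent, ramp
#' ascent/descent, stopped) with distinct cadences and intensities. The
#' "stopped" mode has near-zero oscillation amplitude.
#'
#' @return Named list of [activity_profile()] objects.
#' @export
default_activities <- function() {
  profs <- list(
    activity_profile("level_walk",    1.10, intensity = 1.00, duration_range = c(4, 8)),
    activity_profile("stair_ascent",  0.75, intensity = 1.15, duration_range = c(3, 6)),
    activity_profile("stair_descent", 0.85, intensity = 1.05, duration_range = c(3, 6)),
    activity_profile("ramp_ascent",   0.95, intensity = 0.95, duration_range = c(3, 7)),
    activity_profile("ramp_descent",  1.05, intensity = 0.90, duration_range = c(3, 7)),
    activity_profile("stopped",       0.80, intensity = 0.02, duration_range = c(2, 4))
  )
  stats::setNames(profs, vapply(profs, `[[`, "", "name"))
}

#' Default activity schedule for a synthetic recording
#'
#' A schedule is a list of `(profile, duration)` stages executed in order,
#' with abrupt activity switches softened by a short cross-fade. The default
#' covers a walking bout, a stair ascent and a ramp descent.
#'
#' @param durations Optional named numeric vector of stage durations in
#'   seconds (names must be activities from [default_activities()]).
#' @return A list of stages, each `list(profile = , duration = )`.
#' @export
default_schedule <- function(durations = c(level_walk = 5, stair_ascent = 4, ramp_descent = 4)) {
  acts <- default_activities()
  bad <- setdiff(names(durations), names(acts))
  if (length(bad)) {
    abort_config(paste0("unknown activities in schedule: ", paste(bad, collapse = ", ")))
  }
  purrr::map2(
    names(durations), unname(durations),
    function(nm, d) list(profile = acts[[nm]], duration = d)
  )
}

#' Subject-level generator parameters
#'
#' Captures inter-subject variation: an overall amplitude multiplier,
#' per-channel phase offsets, a sensor noise level, and the gain of the
#' deterministic input-to-target coupling.
#'
#' @param subject_id Subject label.
#' @param amplitude_scale Positive unitless multiplier on oscillation
#'   amplitudes.
#' @param phase_offsets Numeric vector of per-input-channel phase offsets
#'   in radians (length 30).
#' @param noise_sd Non-negative Gaussian noise standard deviation, in
#'   channel units, applied to inputs and targets.
#' @param coupling_gain Positive gain of the lagged input-to-target
#'   combination.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id, amplitude_scale = 1,
                           phase_offsets = rep(0, 30), noise_sd = 0.05,
                           coupling_gain = 1) {
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0")
  if (amplitude_scale <= 0) abort_config("`amplitude_scale` must be > 0")
  if (coupling_gain <= 0) abort_config("`coupling_gain` must be > 0")
  if (length(phase_offsets) != length(input_channel_names())) {
    abort_shape("`phase_offsets` must have one entry per input channel")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      amplitude_scale = amplitude_scale,
      phase_offsets = phase_offsets,
      noise_sd = noise_sd,
      coupling_gain = coupling_gain
    ),
    class = "subject_params"
  )
}

# Anatomy-driven base phase per channel: the cross-channel phase relations
# of gait are largely conserved across people, so subjects share these base
# phases and differ only by a moderate per-channel deviation.
channel_base_phases <- function() {
  ch <- seq_along(input_channel_names())
  2 * pi * ((ch * 13L) %% 30L) / 30
}

# Draw subject parameters reproducibly from a cohort seed and subject index.
draw_subject_params <- function(cohort_seed, i, noise_sd = 0.05) {
  with_seed(derive_seed(cohort_seed, i), {
    subject_params(
      subject_id = sprintf("S%02d", i),
      amplitude_scale = stats::runif(1, 0.85, 1.15),
      phase_offsets = channel_base_phases() +
        stats::rnorm(length(input_channel_names()), sd = 0.3),
      noise_sd = noise_sd,
      coupling_gain = max(0.5, stats::rnorm(1, mean = 1, sd = 0.005))
    )
  })
}
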