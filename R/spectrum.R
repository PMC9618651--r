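#' One-sided power spectrum of a series
#'
#' Discrete Fourier power spectrum with the mean removed before the
#' transform (no taper window; the full trace is one segment). Powers are
#' scaled so that the sum over bins equals the series' population variance
#' (Parseval identity), which makes band fractions directly interpretable.
#'
#' @param x Numeric series, length >= 2.
#' @param fs Sampling frequency, Hz.
#' @param demean Remove the mean before transforming (default TRUE; the DC
#'   bin is then zero).
#' @return A `spectrum_report` tibble (`freq` in Hz, `power` per bin) with
#'   attributes `total_power`, `fs` and `n`.
#' @export
#' @examples
#' sp <- power_spectrum(sin(2 * pi * 3 * (0:999) / 100), fs = 100)
#' sp$freq[which.max(sp$power)]  # 3 Hz
power_spectrum <- function(x, fs, demean = TRUE) {
  n <- length(x)
  if (n < 2L) abort_shape("series must have at least two samples")
  if (fs <= 0) abort_config("`fs` must be positive")
  if (demean) x <- x - mean(x)
  X <- stats::fft(x)
  p_full <- Mod(X)^2 / n^2
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)           # bins 0 .. n/2
  power <- p_full[idx]
  # Double every bin that has a conjugate twin (not DC, not Nyquist for even n).
  twin <- rep(TRUE, half + 1L)
  twin[1L] <- FALSE
  if (n %% 2 == 0) twin[half + 1L] <- FALSE
  power[twin] <- 2 * power[twin]
  out <- tibble::tibble(freq = (idx - 1L) * fs / n, power = power)
  attr(out, "total_power") <- sum(power)
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  class(out) <- c("spectrum_report", class(out))
  out
}

#' Fraction of spectral power inside a frequency band
#'
#' Fraction of total power in `[f_lo, f_hi)`; when `f_hi` reaches the
#' Nyquist frequency the Nyquist bin is included so the full band
#' `[0, fs/2]` integrates to 1.
#'
#' @param spec A `spectrum_report` from [power_spectrum()].
#' @param f_lo,f_hi Band boundaries in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Scalar fraction in `[0, 1]` (0 for an all-zero spectrum).
#' @export
band_power_fraction <- function(spec, f_lo, f_hi) {
  fs <- attr(spec, "fs")
  if (f_lo < 0 || f_hi > fs / 2 + 1e-9 || f_lo >= f_hi) {
    abort_config("band must satisfy 0 <= f_lo < f_hi <= fs/2")
  }
  total <- attr(spec, "total_power")
  if (total <= 0) return(0)
  sel <- if (f_hi >= fs / 2 - 1e-9) {
    spec$freq >= f_lo
  } else {
    spec$freq >= f_lo & spec$freq < f_hi
  }
  sum(spec$power[sel]) / total
}

#' Compare the spectral content of predictions against ground truth
#'
#' Splits each signal's power at a boundary frequency (default 6 Hz, below
#' which gait signals carry their discriminative content) and tabulates
#' below/above-band power and the high-band fraction per signal, plus the
#' pairwise differences in high-band fraction. Less high-band power in a
#' model's predictions indicates less high-frequency noise.
#'
#' @param truth Ground-truth series.
#' @param pred_a,pred_b Two prediction series of the same length.
#' @param fs Sampling frequency, Hz.
#' @param boundary Band boundary, Hz.
#' @param labels Length-3 signal labels.
#' @return A tibble with one row per signal (`power_below`, `power_above`,
#'   `frac_above`) and a `differences` attribute holding the pairwise
#'   high-band fraction differences.
#' @export
compare_spectra <- function(truth, pred_a, pred_b, fs, boundary = 6,
                            labels = c("truth", "pred_a", "pred_b")) {
  if (length(truth) != length(pred_a) || length(truth) != length(pred_b)) {
    abort_shape("all series must have equal lengths")
  }
  sigs <- stats::setNames(list(truth, pred_a, pred_b), labels)
  rows <- purrr::imap_dfr(sigs, function(x, nm) {
    sp <- power_spectrum(x, fs = fs)
    total <- attr(sp, "total_power")
    frac_hi <- band_power_fraction(sp, boundary, fs / 2)
    tibble::tibble(
      signal = nm,
      power_below = total * (1 - frac_hi),
      power_above = total * frac_hi,
      frac_above = frac_hi
    )
  })
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  diffs <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(
      pair = paste(p, collapse = " - "),
      d_frac_above = rows$frac_above[rows$signal == p[1]] -
        rows$frac_above[rows$signal == p[2]]
    )
  })
  attr(rows, "differences") <- diffs
  attr(rows, "boundary") <- boundary
  rows
}
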