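test_that("resultant acceleration matches the element-wise norm oracle", {
  expect_equal(resultant_acceleration(3, 4, 0), 5)
  expect_equal(resultant_acceleration(0, 0, 0), 0)
  set.seed(1)
  ax <- rnorm(1000); ay <- rnorm(1000); az <- rnorm(1000)
  oracle <- vapply(seq_len(1000), function(i) sqrt(ax[i]^2 + ay[i]^2 + az[i]^2), 0)
  expect_equal(resultant_acceleration(ax, ay, az), oracle, tolerance = 1e-12)
  expect_error(resultant_acceleration(1:3, 1:2, 1:3), class = "gaitattn_error_shape")
})

test_that("moving average smooths as a centred window with symmetric edge shrink", {
  expect_equal(moving_average_smooth(rep(3.5, 10), 5), rep(3.5, 10))
  ramp <- seq(0, 9)
  expect_equal(moving_average_smooth(ramp, 5)[3:8], ramp[3:8])
  impulse <- c(rep(0, 5), 1, rep(0, 5))
  sm <- moving_average_smooth(impulse, 5)
  expect_equal(sm[4:8], rep(0.2, 5))
  expect_equal(sm[c(1:3, 9:11)], rep(0, 6))
  # direct convolution oracle on random input (interior)
  set.seed(2)
  x <- rnorm(50)
  oracle <- vapply(3:48, function(i) mean(x[(i - 2):(i + 2)]), 0)
  expect_equal(moving_average_smooth(x, 5)[3:48], oracle, tolerance = 1e-12)
  # symmetric shrink at the edges keeps the window centred
  expect_equal(moving_average_smooth(x, 5)[2], mean(x[1:3]))
  expect_error(moving_average_smooth(x, 4), class = "gaitattn_error_config")
})

test_that("normalization is a z-score fitted on training data only", {
  set.seed(3)
  df <- tibble::tibble(!!!stats::setNames(
    lapply(1:30, function(i) rnorm(200, mean = i, sd = i / 3)),
    input_channel_names()
  ))
  stats <- fit_normalization(df)
  z <- apply_normalization(df, stats)
  expect_equal(unname(colMeans(as.matrix(z))), rep(0, 30), tolerance = 1e-9)
  expect_equal(unname(apply(as.matrix(z), 2, sd)), rep(1, 30), tolerance = 1e-9)
  # a test row equal to the training mean maps to all zeros
  row0 <- tibble::as_tibble(as.list(stats::setNames(stats$mean, stats$channel)))
  expect_equal(unname(unlist(apply_normalization(row0, stats))), rep(0, 30),
               tolerance = 1e-12)
  df$rankle_acc_x <- 1
  expect_error(fit_normalization(df), "rankle_acc_x",
               class = "gaitattn_error_config")
})

test_that("sliding windows enumerate every start index and never cross subjects", {
  set.seed(4)
  for (case in list(c(N = 16, T = 15), c(N = 100, T = 15), c(N = 37, T = 6))) {
    N <- case[["N"]]; T <- case[["T"]]
    df <- tibble::tibble(subject = rep("A", N))
    for (ch in input_channel_names()) df[[ch]] <- rnorm(N)
    for (ch in target_channel_names()) df[[ch]] <- rnorm(N)
    wd <- sliding_window_resample(df, window = T)
    expect_equal(dim(wd$x), c(N - T, T, 30))
    expect_equal(dim(wd$y), c(N - T, 2))
    # index-arithmetic oracle: every emitted pair equals the raw slice
    X <- as.matrix(df[input_channel_names()])
    Y <- as.matrix(df[target_channel_names()])
    for (i in sample(N - T, min(5, N - T))) {
      expect_equal(wd$x[i, , ], unname(X[i:(i + T - 1), ]), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(unname(wd$y[i, ]), unname(Y[i + T, ]), tolerance = 1e-12)
    }
  }
})

test_that("windows respect subject boundaries and short segments are skipped", {
  set.seed(5)
  mk <- function(subject, n) {
    df <- tibble::tibble(subject = rep(subject, n))
    for (ch in input_channel_names()) df[[ch]] <- rnorm(n)
    for (ch in target_channel_names()) df[[ch]] <- rnorm(n)
    df
  }
  df <- dplyr::bind_rows(mk("A", 20), mk("B", 12), mk("C", 5))
  expect_warning(wd <- sliding_window_resample(df, window = 6), "skipped")
  expect_equal(n_points(wd), (20 - 6) + (12 - 6))
  expect_setequal(unique(wd$provenance$subject), c("A", "B"))
  # every window stays inside one subject's rows
  for (i in seq_len(n_points(wd))) {
    rows <- wd$provenance$window_start[i]:wd$provenance$target_row[i]
    expect_length(unique(df$subject[rows]), 1)
  }
})

test_that("subject split holds out whole subjects and splits points 85/15", {
  cohort <- tiny_cohort(6, seed = 31)
  prep <- prepare_windows(cohort, window = 10,
                          spec = split_spec(c("S05", "S06"), shuffle_seed = 2))
  expect_setequal(unique(prep$test$provenance$subject), c("S05", "S06"))
  rest <- c(prep$train$provenance$subject, prep$validation$provenance$subject)
  expect_length(intersect(unique(rest), c("S05", "S06")), 0)
  n_rest <- n_points(prep$train) + n_points(prep$validation)
  expect_equal(n_points(prep$validation), floor(0.15 * n_rest))
  # counting oracle on a constructed 1000-point set
  df <- tibble::tibble(subject = rep(c("A", "B"), each = 755))
  set.seed(6)
  for (ch in input_channel_names()) df[[ch]] <- rnorm(1510)
  for (ch in target_channel_names()) df[[ch]] <- rnorm(1510)
  wd <- sliding_window_resample(df, window = 5)  # 2 x 750 points
  sp <- split_by_subject(wd, split_spec("B", validation_fraction = 0.15, shuffle_seed = 1))
  expect_equal(n_points(sp$validation), floor(0.15 * 750))
  expect_equal(n_points(sp$train), 750 - floor(0.15 * 750))
  expect_equal(n_points(sp$test), 750)
})

test_that("shuffling is deterministic in the seed and differs across seeds", {
  cohort <- tiny_cohort(3, seed = 41)
  wd <- sliding_window_resample(
    apply_normalization(dplyr::bind_rows(purrr::map(cohort, tibble::as_tibble)),
                        fit_normalization(dplyr::bind_rows(purrr::map(cohort, tibble::as_tibble)))),
    window = 8
  )
  a <- split_by_subject(wd, split_spec("S03", shuffle_seed = 5))
  b <- split_by_subject(wd, split_spec("S03", shuffle_seed = 5))
  c_ <- split_by_subject(wd, split_spec("S03", shuffle_seed = 6))
  expect_identical(a$train$provenance, b$train$provenance)
  expect_false(identical(a$train$provenance, c_$train$provenance))
  expect_error(split_by_subject(wd, split_spec("S99")), class = "gaitattn_error_config")
})

test_that("windowing provenance reconstructs the original row order", {
  cohort <- tiny_cohort(2, seed = 51)
  df <- dplyr::bind_rows(purrr::map(cohort, tibble::as_tibble))
  wd <- sliding_window_resample(df, window = 12)
  # target rows of each subject enumerate the contiguous tail of its rows
  for (s in unique(df$subject)) {
    rows <- which(df$subject == s)
    got <- sort(wd$provenance$target_row[wd$provenance$subject == s])
    expect_equal(got, rows[-seq_len(12)])
  }
})

test_that("Butterworth low-pass: unit DC gain, -3 dB cutoff, strong stopband", {
  fs <- 100
  t <- (0:1999) / fs
  expect_equal(butterworth_lowpass(rep(2.5, 500)), rep(2.5, 500), tolerance = 1e-6)
  # single-pass magnitude response of the designed filter
  bf <- signal::butter(2, 6 / (fs / 2), type = "low")
  hz <- function(f) {
    w <- 2 * pi * f / fs
    abs(sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
          sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1))))
  }
  expect_equal(hz(6), 1 / sqrt(2), tolerance = 0.02)
  expect_lt(hz(20), 0.12)
  # zero-phase application attenuates a 20 Hz tone even harder
  x20 <- sin(2 * pi * 20 * t)
  y20 <- butterworth_lowpass(x20, cutoff = 6, fs = fs)
  mid <- 500:1500
  expect_lt(max(abs(y20[mid])) / max(abs(x20[mid])), 0.12)
  expect_error(butterworth_lowpass(x20, cutoff = 60, fs = fs),
               class = "gaitattn_error_config")
})

test_that("no subject leaks across the split and stats come from training subjects", {
  cohort <- tiny_cohort(4, seed = 61)
  prep <- prepare_windows(cohort, window = 10, spec = split_spec("S04", shuffle_seed = 3))
  expect_true(gaitattn:::assert_no_leakage(prep[c("train", "validation", "test")]))
  # stats reproduce exactly from the non-test subjects' smoothed rows
  rows <- dplyr::bind_rows(purrr::map(cohort[c("S01", "S02", "S03")], function(r) {
    tibble::as_tibble(smooth_targets(r))
  }))
  expect_equal(prep$stats, fit_normalization(rows), tolerance = 1e-12)
})

test_that("windowed datasets round-trip through the binary container", {
  cohort <- tiny_cohort(2, seed = 71)
  prep <- prepare_windows(cohort, window = 6, spec = split_spec("S02", shuffle_seed = 1))
  path <- file.path(withr::local_tempdir(), "train")
  write_windowed(prep$train, path)
  back <- read_windowed(path)
  expect_equal(back$x, prep$train$x, tolerance = 0)
  expect_equal(back$y, prep$train$y, tolerance = 0)
  expect_equal(back$provenance$subject, prep$train$provenance$subject)
  expect_identical(attr(back, "stats_hash"), attr(prep$train, "stats_hash"))
})
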