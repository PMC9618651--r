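# Shared fixtures: everything is generated in code at test time.

tiny_cohort <- function(n = 3, seed = 11,
                        durations = c(level_walk = 4, stair_ascent = 3)) {
  generate_cohort(n, schedule = default_schedule(durations), seed = seed)
}

# A small recording with zero noise and no outliers: targets are an exact
# function of the lagged inputs.
clean_recording <- function(seed = 5, durations = c(level_walk = 4)) {
  generate_subject(
    subject_params("S01", noise_sd = 0),
    default_schedule(durations),
    seed = seed, outlier_rate = 0
  )
}

# Small architectures for fast forward/backward tests.
tiny_attention_spec <- function(window = 5, n_inputs = 3) {
  model_spec("branched", attention = TRUE, bidirectional = TRUE,
             recurrent_widths = c(6, 5), dense_widths = c(7, 1),
             scorer_widths = c(4, 1), window = window, n_inputs = n_inputs)
}

tiny_branched_spec <- function(window = 5, n_inputs = 3) {
  model_spec("branched", attention = FALSE, bidirectional = TRUE,
             recurrent_widths = c(6, 5), dense_widths = c(7, 1),
             window = window, n_inputs = n_inputs)
}

tiny_unbranched_spec <- function(window = 5, n_inputs = 3, bidirectional = FALSE) {
  model_spec("unbranched", attention = FALSE, bidirectional = bidirectional,
             recurrent_widths = c(6), dense_widths = c(7, 2),
             window = window, n_inputs = n_inputs)
}

random_window_array <- function(n, window, features, seed = 1) {
  withr_seed <- function(code) code
  set.seed(seed)
  array(stats::rnorm(n * window * features), c(n, window, features))
}

# Finite-difference gradient of a smooth probe loss (random linear
# functional of the outputs) w.r.t. a sampled subset of parameters; the
# independent oracle for the backward pass. A smooth probe keeps central
# differences clean; the MAPE loss gradient itself is checked separately.
numeric_grad_check <- function(spec, n = 4, n_probe = 40, eps = 1e-5, seed = 42) {
  set.seed(seed)
  model <- build_model(spec, seed = 3)
  x <- array(stats::rnorm(n * spec$window * spec$n_inputs),
             c(n, spec$window, spec$n_inputs))
  R <- matrix(stats::rnorm(n * 2), n, 2)
  lossfun <- function(m) {
    fw <- gaitattn:::model_forward(m, x)
    sum(R * fw$yhat)
  }
  fw <- gaitattn:::model_forward(model, x, cache = TRUE)
  gr <- gaitattn:::model_backward(model, fw, R)

  flat <- function(tree, prefix = list()) {
    if (!is.list(tree)) return(list(list(path = prefix, len = length(tree))))
    out <- list()
    keys <- if (is.null(names(tree))) seq_along(tree) else names(tree)
    for (k in keys) out <- c(out, flat(tree[[k]], c(prefix, list(k))))
    out
  }
  getleaf <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  setleaf <- function(tree, path, i, d) {
    if (!length(path)) {
      tree[i] <- tree[i] + d
      return(tree)
    }
    tree[[path[[1]]]] <- setleaf(tree[[path[[1]]]], path[-1], i, d)
    tree
  }
  leaves <- flat(model$params)
  total <- sum(vapply(leaves, `[[`, 0, "len"))
  probes <- sort(sample(total, min(n_probe, total)))
  offsets <- cumsum(c(0, vapply(leaves, `[[`, 0, "len")))
  rel_errs <- vapply(probes, function(k) {
    li <- findInterval(k - 1, offsets, rightmost.closed = FALSE)
    path <- leaves[[li]]$path
    i <- k - offsets[li]
    m1 <- model
    m2 <- model
    m1$params <- setleaf(model$params, path, i, eps)
    m2$params <- setleaf(model$params, path, i, -eps)
    num <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
    ana <- getleaf(gr, path)[i]
    abs(num - ana) / max(abs(num) + abs(ana), 1e-7)
  }, 0)
  max(rel_errs)
}
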