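test_that("spec invariants are enforced", {
  expect_error(model_spec("branched", attention = TRUE, recurrent_widths = c(8, 8, 8)),
               class = "gaitattn_error_config")
  expect_error(model_spec("branched", dense_widths = c(16, 2)),
               class = "gaitattn_error_config")
  expect_error(model_spec("unbranched", dense_widths = c(16, 1)),
               class = "gaitattn_error_config")
  expect_error(model_spec("branched", attention = TRUE, scorer_widths = c(8, 2)),
               class = "gaitattn_error_config")
})

test_that("topology fixes the number of dense heads", {
  m_b <- build_model(tiny_branched_spec(), seed = 1)
  m_u <- build_model(tiny_unbranched_spec(), seed = 1)
  expect_length(m_b$params$heads, 2)
  expect_length(m_u$params$heads, 1)
  # unbranched: only the last layer emits both outputs
  expect_equal(ncol(m_u$params$heads[[1]][[2]]$W), 2)
})

test_that("attention scores match an exponentiate-and-normalize oracle", {
  set.seed(7)
  for (trial in 1:25) {
    T_ <- sample(3:12, 1)
    d <- sample(2:8, 1)
    H <- matrix(rnorm(T_ * d), T_, d)
    w <- rnorm(d)
    scorer <- function(h) sum(w * h) + 0.3
    alpha <- attention_scores(H, scorer)
    e <- vapply(seq_len(T_), function(t) sum(w * H[t, ]) + 0.3, 0)
    oracle <- exp(e) / sum(exp(e))
    expect_equal(alpha, oracle, tolerance = 1e-9)
    expect_equal(sum(alpha), 1, tolerance = 1e-9)
    expect_true(all(alpha >= 0 & alpha <= 1))
  }
})

test_that("softmax scores are shift-invariant and equal scores give 1/T", {
  H <- matrix(rnorm(40), 8, 5)
  w <- rnorm(5)
  a1 <- attention_scores(H, function(h) sum(w * h))
  a2 <- attention_scores(H, function(h) sum(w * h) + 123.4)
  expect_equal(a1, a2, tolerance = 1e-9)
  H_same <- matrix(rep(rnorm(5), each = 6), 6, 5)
  expect_equal(attention_scores(H_same, function(h) sum(h)), rep(1 / 6, 6),
               tolerance = 1e-12)
})

test_that("permuting timesteps permutes attention weights identically", {
  set.seed(8)
  H <- matrix(rnorm(6 * 4), 6, 4)
  w <- rnorm(4)
  scorer <- function(h) tanh(sum(w * h))
  alpha <- attention_scores(H, scorer)
  perm <- sample(6)
  expect_equal(attention_scores(H[perm, ], scorer), alpha[perm], tolerance = 1e-12)
})

test_that("attention rescale and context match brute-force loops", {
  set.seed(9)
  H <- matrix(rnorm(7 * 5), 7, 5)
  e <- rnorm(7)
  alpha <- exp(e) / sum(exp(e))
  resc <- apply_attention_rescale(H, alpha)
  ctx <- apply_attention_context(H, alpha)
  resc_o <- H
  ctx_o <- rep(0, 5)
  for (t in 1:7) {
    for (j in 1:5) resc_o[t, j] <- alpha[t] * H[t, j]
    ctx_o <- ctx_o + alpha[t] * H[t, ]
  }
  expect_equal(resc, resc_o, tolerance = 1e-12)
  expect_equal(ctx, ctx_o, tolerance = 1e-12)
  # limits: uniform weights scale rows by 1/T / average rows; one-hot selects
  expect_equal(apply_attention_rescale(H, rep(1 / 7, 7)), H / 7, tolerance = 1e-12)
  expect_equal(apply_attention_context(H, rep(1 / 7, 7)), colMeans(H), tolerance = 1e-12)
  onehot <- c(0, 0, 1, 0, 0, 0, 0)
  expect_equal(apply_attention_context(H, onehot), H[3, ], tolerance = 1e-12)
  expect_equal(apply_attention_rescale(H, onehot)[-3, ], matrix(0, 6, 5),
               ignore_attr = TRUE)
  expect_error(apply_attention_context(H, alpha[-1]), class = "gaitattn_error_shape")
})

test_that("forward passes normalize attention weights and are deterministic", {
  spec <- tiny_attention_spec()
  model <- build_model(spec, seed = 5)
  x <- random_window_array(6, spec$window, spec$n_inputs, seed = 10)
  out1 <- predict(model, x, attention = TRUE)
  out2 <- predict(model, x, attention = TRUE)
  expect_identical(out1$pred, out2$pred)
  expect_equal(rowSums(out1$alpha1), rep(1, 6), tolerance = 1e-6)
  expect_equal(rowSums(out1$alpha2), rep(1, 6), tolerance = 1e-6)
  expect_true(all(out1$alpha1 >= 0 & out1$alpha1 <= 1))
  # identical windows in a batch give identical outputs
  x_same <- x
  for (i in 2:6) x_same[i, , ] <- x_same[1, , ]
  p <- predict(model, x_same)
  expect_equal(p, p[rep(1, 6), ], tolerance = 1e-12, ignore_attr = TRUE)
  # rebuilt with the same seed: identical parameters
  expect_identical(build_model(spec, seed = 5)$params, model$params)
})

test_that("a constant scorer reduces the context vector to the sequence mean", {
  spec <- tiny_attention_spec()
  model <- build_model(spec, seed = 6)
  # force both scorers to output a constant
  for (s in c("scorer1", "scorer2")) {
    for (i in seq_along(model$params[[s]])) {
      model$params[[s]][[i]]$W[] <- 0
    }
  }
  x <- random_window_array(3, spec$window, spec$n_inputs, seed = 11)
  fw <- gaitattn:::model_forward(model, x, cache = TRUE)
  expect_equal(fw$alpha2, matrix(1 / spec$window, 3, spec$window), tolerance = 1e-12)
  HL <- fw$cache$H_outs[[2]]
  mean_H <- apply(HL, c(1, 2), mean)
  expect_equal(fw$cache$ctx, mean_H, tolerance = 1e-9)
})

test_that("parameter counts match closed-form oracles", {
  # dense layer: (n_in + 1) * n_out
  dense_only <- gaitattn:::init_dense(c(2), 4)
  expect_equal(sum(lengths(purrr::flatten(dense_only))), 10)
  # unidirectional gated cell: 4 * (u * (n + u) + u), n = 4, u = 3 -> 96
  uni <- model_spec("unbranched", bidirectional = FALSE, recurrent_widths = 3,
                    dense_widths = c(2), window = 5, n_inputs = 4, n_outputs = 2)
  m_uni <- build_model(uni, seed = 1)
  rnn_count <- sum(lengths(purrr::flatten(m_uni$params$rnn[[1]])))
  expect_equal(rnn_count, 96)
  # bidirectional doubles the recurrent parameters
  bi <- model_spec("unbranched", bidirectional = TRUE, recurrent_widths = 3,
                   dense_widths = c(2), window = 5, n_inputs = 4, n_outputs = 2)
  m_bi <- build_model(bi, seed = 1)
  expect_equal(sum(lengths(purrr::flatten(m_bi$params$rnn[[1]]))), 192)
})

test_that("branched and unbranched counts differ by exactly the extra head", {
  b <- model_spec("branched", recurrent_widths = c(8, 6), dense_widths = c(5, 1),
                  window = 5, n_inputs = 4)
  u <- model_spec("unbranched", recurrent_widths = c(8, 6), dense_widths = c(5, 1 * 2),
                  window = 5, n_inputs = 4)
  d_head <- 6 * 2  # bidirectional last layer
  # counting oracle: branched has two full heads; unbranched shares the
  # hidden layer and only widens the output layer
  extra_branch <- (d_head + 1) * 5 + (5 + 1) * 1
  extra_out <- (5 + 1) * 1
  expect_equal(count_parameters(b) - count_parameters(u), extra_branch - extra_out)
})

test_that("the attention preset needs at most half the baseline's parameters", {
  p_att <- count_parameters(spec_branched_attention())
  p_base <- count_parameters(spec_branched_baseline())
  expect_lte(p_att, 0.5 * p_base)
  # larger unbranched preset roughly doubles the smaller one
  p_small <- count_parameters(spec_unbranched_baseline("smaller"))
  p_large <- count_parameters(spec_unbranched_baseline("larger"))
  expect_gt(p_large / p_small, 1.8)
  expect_lt(p_large / p_small, 2.2)
})

test_that("window length presets follow the studied configurations", {
  expect_equal(spec_branched_attention()$window, 25)
  expect_equal(spec_branched_baseline()$window, 15)
  m <- build_model(spec_branched_attention(), seed = 1)
  x <- random_window_array(2, 25, 30, seed = 12)
  expect_silent(predict(m, x))
  expect_error(predict(m, random_window_array(2, 15, 30, seed = 12)),
               class = "gaitattn_error_shape")
})

test_that("output_bias initialization sets the untrained prediction level", {
  spec <- tiny_branched_spec()
  m <- build_model(spec, seed = 3, output_bias = c(9.5, 10.5))
  x <- random_window_array(50, spec$window, spec$n_inputs, seed = 13)
  p <- predict(m, x)
  expect_equal(unname(colMeans(p)), c(9.5, 10.5), tolerance = 1.5)
})
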