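#' Declare a motion-estimation model architecture
#'
#' A `model_spec` fully describes one of the studied architectures: an
#' unbranched baseline (single dense head emitting all outputs), a branched
#' baseline (shared recurrent trunk, one dense head and loss per output),
#' or the branched attention model (two bidirectional recurrent layers with
#' a timestep-rescaling attention layer between them and a context-vector
#' attention layer after the second).
#'
#' @param topology `"branched"` or `"unbranched"`.
#' @param attention Logical; include the two temporal attention layers.
#'   Requires exactly two recurrent layers.
#' @param bidirectional Logical; process each window forward and backward
#'   and concatenate the per-timestep hidden states.
#' @param recurrent_widths Integer vector of hidden sizes, one per stacked
#'   recurrent layer (per direction). Defaults are desk-scale: large enough
#'   to learn the synthetic coupling, small enough to train in minutes on a
#'   single CPU.
#' @param dense_widths Integer vector of dense-head layer widths including
#'   the output layer: the last entry must be 1 for branched heads and
#'   `n_outputs` for the unbranched head. Hidden dense layers use the
#'   rectifier activation; the output layer is linear (regression).
#' @param scorer_widths Widths of the attention scoring perceptron
#'   including its scalar output (last entry must be 1); hidden layers use
#'   tanh.
#' @param window Input window length T in timesteps.
#' @param n_inputs,n_outputs Input/output channel counts.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("branched", attention = TRUE, window = 25)
model_spec <- function(topology = c("branched", "unbranched"),
                       attention = FALSE, bidirectional = TRUE,
                       recurrent_widths = c(64, 32),
                       dense_widths = NULL,
                       scorer_widths = c(16, 1),
                       window = 15, n_inputs = 30, n_outputs = 2) {
  topology <- match.arg(topology)
  dense_widths <- dense_widths %||%
    if (topology == "branched") c(32, 16, 1) else c(32, 16, n_outputs)
  if (attention && length(recurrent_widths) != 2L) {
    abort_config("the attention architecture requires exactly two recurrent layers")
  }
  if (!length(recurrent_widths) || any(recurrent_widths < 1)) {
    abort_config("`recurrent_widths` must be positive integers")
  }
  if (topology == "branched" && utils::tail(dense_widths, 1) != 1) {
    abort_config("branched heads must end in a single output unit")
  }
  if (topology == "unbranched" && utils::tail(dense_widths, 1) != n_outputs) {
    abort_config("the unbranched head must end in `n_outputs` units")
  }
  if (attention && utils::tail(scorer_widths, 1) != 1) {
    abort_config("the attention scorer must output one scalar score per timestep")
  }
  if (!is_count(window) || window < 1) abort_config("`window` must be a positive integer")
  structure(
    list(
      topology = topology,
      attention = isTRUE(attention),
      bidirectional = isTRUE(bidirectional),
      recurrent_widths = as.integer(recurrent_widths),
      dense_widths = as.integer(dense_widths),
      scorer_widths = as.integer(scorer_widths),
      window = as.integer(window),
      n_inputs = as.integer(n_inputs),
      n_outputs = as.integer(n_outputs)
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s%s %s, T = %d, recurrent [%s], dense [%s]%s\n",
    x$topology,
    if (x$attention) " + attention" else "",
    if (x$bidirectional) "Bi-LSTM" else "LSTM",
    x$window,
    paste(x$recurrent_widths, collapse = ", "),
    paste(x$dense_widths, collapse = ", "),
    if (x$attention) sprintf(", scorer [%s]", paste(x$scorer_widths, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Preset architectures
#'
#' The four architectures compared in this package: the branched attention
#' model (window 25), the branched baseline and the smaller/larger
#' unbranched baselines (window 15). The baselines carry wider recurrent
#' layers than the attention model — attention concentrates capacity on
#' informative timesteps, so its preset uses at most half the parameters of
#' the branched baseline — and the larger unbranched preset roughly doubles
#' the smaller one.
#'
#' @param window Input window length; defaults follow the architecture.
#' @return A [model_spec()].
#' @export
spec_branched_attention <- function(window = 25) {
  model_spec("branched", attention = TRUE, bidirectional = TRUE,
             recurrent_widths = c(64, 32), dense_widths = c(32, 16, 1),
             scorer_widths = c(16, 1), window = window)
}

#' @rdname spec_branched_attention
#' @export
spec_branched_baseline <- function(window = 15) {
  model_spec("branched", attention = FALSE, bidirectional = TRUE,
             recurrent_widths = c(96, 64), dense_widths = c(32, 16, 1),
             window = window)
}

#' @rdname spec_branched_attention
#' @param size `"smaller"` or `"larger"` unbranched baseline.
#' @export
spec_unbranched_baseline <- function(size = c("smaller", "larger"), window = 15) {
  size <- match.arg(size)
  widths <- if (size == "smaller") c(96, 64) else c(140, 92)
  model_spec("unbranched", attention = FALSE, bidirectional = TRUE,
             recurrent_widths = widths, dense_widths = c(32, 16, 2),
             window = window)
}

glorot <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}

init_lstm <- function(n_in, h) {
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
  list(W = glorot(n_in, 4 * h), U = glorot(h, 4 * h), b = b)
}

init_dense <- function(widths, n_in) {
  layers <- list()
  for (w in widths) {
    layers[[length(layers) + 1L]] <- list(W = glorot(n_in, w), b = rep(0, w))
    n_in <- w
  }
  layers
}

#' Build a trainable model from a spec
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases with the
#' forget-gate bias opened at 1) under a recorded seed, so construction is
#' deterministic.
#'
#' @param spec A [model_spec()].
#' @param seed Initialization seed.
#' @param output_bias Optional initial value(s) for the output-layer
#'   bias(es), recycled across outputs. Setting this to the training-target
#'   mean (e.g. `colMeans(train$y)`) starts the regression at the right
#'   order of magnitude — important under a relative-error loss when the
#'   targets sit on a large offset such as gravity — instead of at zero.
#' @return A `motion_model` object holding the spec and parameter arrays.
#' @export
build_model <- function(spec, seed = 1, output_bias = NULL) {
  if (!inherits(spec, "model_spec")) abort_config("`spec` must be a model_spec")
  with_seed(seed, {
    dir_mult <- if (spec$bidirectional) 2L else 1L
    params <- list(rnn = list())
    n_in <- spec$n_inputs
    for (l in seq_along(spec$recurrent_widths)) {
      h <- spec$recurrent_widths[l]
      layer <- list(fwd = init_lstm(n_in, h))
      if (spec$bidirectional) layer$bwd <- init_lstm(n_in, h)
      params$rnn[[l]] <- layer
      n_in <- h * dir_mult
    }
    if (spec$attention) {
      d1 <- spec$recurrent_widths[1] * dir_mult
      d2 <- spec$recurrent_widths[2] * dir_mult
      params$scorer1 <- init_dense(spec$scorer_widths, d1)
      params$scorer2 <- init_dense(spec$scorer_widths, d2)
    }
    d_head <- utils::tail(spec$recurrent_widths, 1) * dir_mult
    if (spec$topology == "branched") {
      params$heads <- lapply(seq_len(spec$n_outputs), function(k) {
        init_dense(spec$dense_widths, d_head)
      })
    } else {
      params$heads <- list(init_dense(spec$dense_widths, d_head))
    }
    if (!is.null(output_bias)) {
      ob <- rep_len(as.numeric(output_bias), spec$n_outputs)
      if (spec$topology == "branched") {
        for (k in seq_len(spec$n_outputs)) {
          last <- length(params$heads[[k]])
          params$heads[[k]][[last]]$b <- ob[k]
        }
      } else {
        last <- length(params$heads[[1]])
        params$heads[[1]][[last]]$b <- ob
      }
    }
    structure(
      list(spec = spec, params = params, init_seed = as.integer(seed)),
      class = "motion_model"
    )
  })
}

#' @export
print.motion_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %s trainable parameters (init seed %d)\n",
              format(count_parameters(x), big.mark = ","), x$init_seed))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in a built model (or in the model a
#' spec would build).
#'
#' @param model A `motion_model` or `model_spec`.
#' @return Integer count.
#' @export
#' @examples
#' count_parameters(spec_branched_attention())
count_parameters <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model, seed = 0)
  if (!inherits(model, "motion_model")) abort_config("`model` must be a motion_model or model_spec")
  leaf_sum <- function(x) {
    if (is.list(x)) sum(vapply(x, leaf_sum, 0)) else length(x)
  }
  as.integer(leaf_sum(model$params))
}

# Forward pass of a dense stack on a plain matrix input.
mlp_forward <- function(A, layers, hidden_act = c("relu", "tanh")) {
  hidden_act <- match.arg(hidden_act)
  L <- length(layers)
  for (i in seq_len(L)) {
    Z <- A %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    A <- if (i < L) {
      if (hidden_act == "relu") pmax(Z, 0) else tanh(Z)
    } else {
      Z
    }
  }
  A
}

#' Per-timestep attention scores
#'
#' Applies one shared learnable scoring function to every timestep of a
#' hidden sequence and normalizes the resulting scores with a softmax, so
#' each score lies in \[0, 1\] and they sum to one.
#'
#' @param H Numeric matrix of shape `(T, d)`: per-timestep hidden vectors.
#' @param scorer Either a function mapping a hidden vector to a scalar, or
#'   a list of dense layers `list(W, b)` (tanh hidden activations, linear
#'   scalar output) as stored in a built attention model.
#' @return Numeric vector of T normalized attention weights.
#' @export
#' @examples
#' H <- matrix(rnorm(12), 4, 3)
#' attention_scores(H, function(h) sum(h))
attention_scores <- function(H, scorer) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) abort_shape("hidden sequence is empty")
  e <- if (is.function(scorer)) {
    apply(H, 1L, function(h) as.numeric(scorer(h)))
  } else {
    drop(mlp_forward(H, scorer, hidden_act = "tanh"))
  }
  if (length(e) != nrow(H)) abort_shape("scorer must return one scalar per timestep")
  softmax(e)
}

#' Rescale a hidden sequence by attention weights
#'
#' First attention layer: each timestep's hidden vector is multiplied by
#' its attention weight; the sequence shape is preserved so it can feed the
#' next recurrent layer.
#'
#' @param H Numeric matrix `(T, d)`.
#' @param alpha Attention weights of length T.
#' @return Matrix of the same shape as `H`.
#' @export
apply_attention_rescale <- function(H, alpha) {
  H <- as.matrix(H)
  if (length(alpha) != nrow(H)) abort_shape("`alpha` must have one weight per timestep")
  H * alpha
}

#' Collapse a hidden sequence into an attention context vector
#'
#' Second attention layer: the weighted timestep vectors are summed into a
#' single context vector that feeds the dense head(s).
#'
#' @inheritParams apply_attention_rescale
#' @return Numeric vector of length d.
#' @export
apply_attention_context <- function(H, alpha) {
  H <- as.matrix(H)
  if (length(alpha) != nrow(H)) abort_shape("`alpha` must have one weight per timestep")
  colSums(H * alpha)
}
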