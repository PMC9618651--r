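# Batched network forward / backward passes.
#
# Internally sequences are held as arrays with one time slice per step:
# (batch, features, timesteps). The compiled LSTM kernels consume and
# produce this layout; attention and dense algebra stay in R where the
# work is plain matrix arithmetic.

to_tfirst <- function(x) aperm(x, c(1, 3, 2))  # (N,T,F) -> (N,F,T)

rev_time <- function(a) {
  d3 <- dim(a)[3]
  a[, , d3:1, drop = FALSE]
}

# Expand per-(batch, timestep) weights to the (batch, d, timestep) layout.
expand_alpha <- function(alpha, d) {
  B <- nrow(alpha); T <- ncol(alpha)
  aperm(array(alpha, dim = c(B, T, d)), c(1, 3, 2))
}

bilstm_forward <- function(X3, layer, bidirectional) {
  fwd <- lstm_forward_cpp(X3, layer$fwd$W, layer$fwd$U, layer$fwd$b)
  if (!bidirectional) {
    return(list(H = fwd$H, fwd = fwd, X3 = X3))
  }
  Xr <- rev_time(X3)
  bwd <- lstm_forward_cpp(Xr, layer$bwd$W, layer$bwd$U, layer$bwd$b)
  d <- dim(fwd$H)
  H <- array(0, dim = c(d[1], 2 * d[2], d[3]))
  H[, seq_len(d[2]), ] <- fwd$H
  H[, d[2] + seq_len(d[2]), ] <- rev_time(bwd$H)
  list(H = H, fwd = fwd, bwd = bwd, X3 = X3, Xr = Xr)
}

bilstm_backward <- function(dH, cache, layer, bidirectional) {
  h <- dim(cache$fwd$H)[2]
  gf <- lstm_backward_cpp(dH[, seq_len(h), , drop = FALSE], cache$X3,
                          cache$fwd$H, cache$fwd$C, cache$fwd$G,
                          layer$fwd$W, layer$fwd$U)
  grads <- list(fwd = list(W = gf$dW, U = gf$dU, b = drop(gf$db)))
  dX <- gf$dX
  if (bidirectional) {
    dHb <- rev_time(dH[, h + seq_len(h), , drop = FALSE])
    gb <- lstm_backward_cpp(dHb, cache$Xr, cache$bwd$H, cache$bwd$C,
                            cache$bwd$G, layer$bwd$W, layer$bwd$U)
    grads$bwd <- list(W = gb$dW, U = gb$dU, b = drop(gb$db))
    dX <- dX + rev_time(gb$dX)
  }
  list(dX = dX, grads = grads)
}

mlp_forward_cache <- function(A, layers, hidden_act = "relu") {
  L <- length(layers)
  inputs <- vector("list", L)
  acts <- vector("list", L)
  for (i in seq_len(L)) {
    inputs[[i]] <- A
    Z <- A %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    A <- if (i < L) {
      if (hidden_act == "relu") pmax(Z, 0) else tanh(Z)
    } else {
      Z
    }
    acts[[i]] <- A
  }
  list(out = A, inputs = inputs, acts = acts, hidden_act = hidden_act)
}

mlp_backward <- function(dOut, cache, layers) {
  L <- length(layers)
  grads <- vector("list", L)
  dA <- dOut
  for (i in rev(seq_len(L))) {
    dZ <- if (i < L) {
      if (cache$hidden_act == "relu") {
        dA * (cache$acts[[i]] > 0)
      } else {
        dA * (1 - cache$acts[[i]]^2)
      }
    } else {
      dA
    }
    grads[[i]] <- list(W = crossprod(cache$inputs[[i]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[i]]$W)
  }
  list(dA = dA, grads = grads)
}

# Scorer applied identically to every timestep of a hidden cube.
scorer_forward <- function(H, scorer) {
  d <- dim(H)  # (B, dh, T)
  Hm <- matrix(aperm(H, c(1, 3, 2)), d[1] * d[3], d[2])
  cache <- mlp_forward_cache(Hm, scorer, hidden_act = "tanh")
  list(E = matrix(drop(cache$out), d[1], d[3]), cache = cache, dims = d)
}

scorer_backward <- function(dE, sc, scorer) {
  d <- sc$dims
  back <- mlp_backward(matrix(as.numeric(dE), d[1] * d[3], 1L), sc$cache, scorer)
  dH <- aperm(array(back$dA, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  list(dH = dH, grads = back$grads)
}

softmax_rows_backward <- function(alpha, dAlpha) {
  alpha * (dAlpha - rowSums(alpha * dAlpha))
}

# Full forward pass. `x` is (batch, T, features); returns predictions and,
# when `cache = TRUE`, everything the backward pass needs.
model_forward <- function(model, x, cache = FALSE) {
  spec <- model$spec
  p <- model$params
  dm <- dim(x)
  if (length(dm) != 3L || dm[2] != spec$window || dm[3] != spec$n_inputs) {
    abort_shape(sprintf(
      "input must be shaped (batch, %d, %d); got (%s)",
      spec$window, spec$n_inputs, paste(dm, collapse = ", ")
    ))
  }
  X3 <- to_tfirst(x)
  L <- length(spec$recurrent_widths)
  rnn_caches <- vector("list", L)
  H_outs <- vector("list", L)
  alpha1 <- alpha2 <- NULL
  sc1 <- sc2 <- NULL
  H1 <- NULL

  inp <- X3
  for (l in seq_len(L)) {
    bl <- bilstm_forward(inp, p$rnn[[l]], spec$bidirectional)
    rnn_caches[[l]] <- bl
    H_outs[[l]] <- bl$H
    inp <- bl$H
    if (spec$attention && l == 1L) {
      H1 <- bl$H
      sc1 <- scorer_forward(H1, p$scorer1)
      alpha1 <- softmax_rows(sc1$E)
      inp <- H1 * expand_alpha(alpha1, dim(H1)[2])
    }
  }
  HL <- H_outs[[L]]
  dL <- dim(HL)

  if (spec$attention) {
    sc2 <- scorer_forward(HL, p$scorer2)
    alpha2 <- softmax_rows(sc2$E)
    ctx <- matrix(0, dL[1], dL[2])
    for (t in seq_len(dL[3])) {
      ctx <- ctx + matrix(HL[, , t], dL[1], dL[2]) * alpha2[, t]
    }
  } else if (spec$bidirectional) {
    h <- spec$recurrent_widths[L]
    ctx <- cbind(
      matrix(HL[, seq_len(h), dL[3]], dL[1], h),
      matrix(HL[, h + seq_len(h), 1L], dL[1], h)
    )
  } else {
    ctx <- matrix(HL[, , dL[3]], dL[1], dL[2])
  }

  head_caches <- lapply(p$heads, function(hd) mlp_forward_cache(ctx, hd, "relu"))
  yhat <- do.call(cbind, lapply(head_caches, `[[`, "out"))
  colnames(yhat) <- NULL

  out <- list(yhat = yhat, alpha1 = alpha1, alpha2 = alpha2)
  if (cache) {
    out$cache <- list(
      rnn = rnn_caches, H_outs = H_outs, heads = head_caches,
      sc1 = sc1, sc2 = sc2, alpha1 = alpha1, alpha2 = alpha2,
      H1 = H1, ctx = ctx, rescaled_input = if (spec$attention) inp else NULL
    )
  }
  out
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter, given
# dY = dLoss/dYhat. Returns a gradient tree shaped like model$params.
model_backward <- function(model, fw, dY) {
  spec <- model$spec
  p <- model$params
  cc <- fw$cache
  L <- length(spec$recurrent_widths)
  grads <- list(rnn = vector("list", L))

  dctx <- 0
  grads$heads <- vector("list", length(p$heads))
  for (k in seq_along(p$heads)) {
    dyk <- if (length(p$heads) > 1L) dY[, k, drop = FALSE] else dY
    hb <- mlp_backward(dyk, cc$heads[[k]], p$heads[[k]])
    grads$heads[[k]] <- hb$grads
    dctx <- dctx + hb$dA
  }

  HL <- cc$H_outs[[L]]
  dL <- dim(HL)
  dHL <- array(0, dim = dL)
  if (spec$attention) {
    alpha2 <- cc$alpha2
    dAlpha2 <- matrix(0, dL[1], dL[3])
    for (t in seq_len(dL[3])) {
      dHL[, , t] <- matrix(dHL[, , t], dL[1], dL[2]) + dctx * alpha2[, t]
      dAlpha2[, t] <- rowSums(dctx * matrix(HL[, , t], dL[1], dL[2]))
    }
    dE2 <- softmax_rows_backward(alpha2, dAlpha2)
    sb2 <- scorer_backward(dE2, cc$sc2, p$scorer2)
    grads$scorer2 <- sb2$grads
    dHL <- dHL + sb2$dH
  } else if (spec$bidirectional) {
    h <- spec$recurrent_widths[L]
    dHL[, seq_len(h), dL[3]] <- dctx[, seq_len(h)]
    dHL[, h + seq_len(h), 1L] <- dctx[, h + seq_len(h)]
  } else {
    dHL[, , dL[3]] <- dctx
  }

  dH <- dHL
  for (l in rev(seq_len(L))) {
    bb <- bilstm_backward(dH, cc$rnn[[l]], p$rnn[[l]], spec$bidirectional)
    grads$rnn[[l]] <- bb$grads
    dH <- bb$dX
    if (spec$attention && l == 2L) {
      # dH is the gradient w.r.t. the rescaled sequence alpha1 * H1.
      H1 <- cc$H1
      alpha1 <- cc$alpha1
      d1 <- dim(H1)
      dAlpha1 <- matrix(0, d1[1], d1[3])
      for (t in seq_len(d1[3])) {
        dAlpha1[, t] <- rowSums(matrix(dH[, , t], d1[1], d1[2]) *
                                  matrix(H1[, , t], d1[1], d1[2]))
      }
      dH <- dH * expand_alpha(alpha1, d1[2])
      dE1 <- softmax_rows_backward(alpha1, dAlpha1)
      sb1 <- scorer_backward(dE1, cc$sc1, p$scorer1)
      grads$scorer1 <- sb1$grads
      dH <- dH + sb1$dH
    }
  }
  grads
}

#' Predict target accelerations for windowed data
#'
#' One-step-ahead predictions for every data point, evaluated in chunks.
#'
#' @param object A `motion_model` (or the `model` inside a fitted object).
#' @param newdata A `windowed_dataset` or a 3-D array shaped
#'   `(data points, window, features)`.
#' @param attention If `TRUE` and the model has attention layers, also
#'   return the per-timestep attention weights of both layers.
#' @param batch_size Chunk size for evaluation.
#' @param ... Unused.
#' @return A numeric matrix `(data points, 2)` of predictions, or, with
#'   `attention = TRUE`, a list with elements `pred`, `alpha1`, `alpha2`.
#' @export
predict.motion_model <- function(object, newdata, attention = FALSE,
                                 batch_size = 2048, ...) {
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  if (length(dim(x)) != 3L) abort_shape("`newdata` must be a 3-D array or windowed_dataset")
  n <- dim(x)[1]
  preds <- matrix(0, n, object$spec$n_outputs)
  colnames(preds) <- target_channel_names()[seq_len(object$spec$n_outputs)]
  a1 <- a2 <- if (attention && object$spec$attention) {
    matrix(0, n, object$spec$window)
  } else {
    NULL
  }
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    fw <- model_forward(object, x[idx, , , drop = FALSE])
    preds[idx, ] <- fw$yhat
    if (!is.null(a1)) {
      a1[idx, ] <- fw$alpha1
      a2[idx, ] <- fw$alpha2
    }
  }
  if (!is.null(a1)) list(pred = preds, alpha1 = a1, alpha2 = a2) else preds
}

#' @export
predict.motion_model_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
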