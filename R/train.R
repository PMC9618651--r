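#' Training configuration
#'
#' Bundles the optimization hyperparameters: Adam with an initial learning
#' rate of 0.001, multiplicative learning-rate decay when the validation
#' loss plateaus, early stopping, and an epsilon floor guarding the MAPE
#' loss against division by near-zero targets (resultant accelerations can
#' approach zero when the subject is stopped).
#'
#' @param initial_lr Initial Adam learning rate.
#' @param lr_decay_factor Multiplier applied to the learning rate after a
#'   plateau; in (0, 1).
#' @param lr_patience Epochs without validation improvement before the
#'   learning rate decays.
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param seed Seed governing shuffling and any other training randomness.
#' @param loss_guard_epsilon Denominator floor of the MAPE loss, in target
#'   units.
#' @return A `training_config` object.
#' @export
training_config <- function(initial_lr = 0.001, lr_decay_factor = 0.5,
                            lr_patience = 5, early_stop_patience = 15,
                            batch_size = 256, max_epochs = 100, seed = 1,
                            loss_guard_epsilon = 1e-3) {
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1) {
    abort_config("`lr_decay_factor` must be in (0, 1)")
  }
  if (lr_patience < 1 || early_stop_patience < 1) {
    abort_config("patience values must be >= 1 epoch")
  }
  if (loss_guard_epsilon <= 0) abort_config("`loss_guard_epsilon` must be > 0")
  structure(
    list(
      initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
      lr_patience = as.integer(lr_patience),
      early_stop_patience = as.integer(early_stop_patience),
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      seed = as.integer(seed),
      loss_guard_epsilon = loss_guard_epsilon
    ),
    class = "training_config"
  )
}

#' Mean absolute percentage error
#'
#' `mean(|y - yhat| / max(|y|, epsilon))`, the training loss. The epsilon
#' floor keeps the loss finite when a target value is (near) zero. Returned
#' as a fraction; multiply by 100 to report percent.
#'
#' @param y,yhat Numeric vectors or matrices of equal shape.
#' @param epsilon Denominator floor, target units.
#' @return Scalar loss (fraction).
#' @export
#' @examples
#' mape_loss(c(1, 2), c(1.1, 1.8))  # 0.10
mape_loss <- function(y, yhat, epsilon = 1e-3) {
  if (length(y) == 0L) abort_shape("empty input to mape_loss")
  if (length(y) != length(yhat)) abort_shape("`y` and `yhat` must have equal lengths")
  mean(abs(y - yhat) / pmax(abs(y), epsilon))
}

# Per-output MAPE losses and the gradient of the total training loss.
# Branched models optimize the unweighted sum of per-output losses;
# unbranched models optimize the single average across all outputs.
mape_loss_grad <- function(y, yhat, epsilon, branched) {
  n <- nrow(y)
  denom <- pmax(abs(y), epsilon)
  per_output <- colMeans(abs(y - yhat) / denom)
  scale <- if (branched) n else length(y)
  grad <- sign(yhat - y) / (denom * scale)
  total <- if (branched) sum(per_output) else mean(per_output)
  list(per_output = per_output, total = total, grad = grad)
}

# Apply f over corresponding leaves of parameter trees. Named levels are
# paired by name (gradient trees may order their components differently
# from the parameter tree), unnamed levels by position.
map_tree <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    nm <- names(trees[[1]])
    keys <- if (is.null(nm)) seq_along(trees[[1]]) else nm
    out <- vector("list", length(keys))
    names(out) <- nm
    for (i in seq_along(keys)) {
      out[[i]] <- do.call(map_tree, c(list(f), lapply(trees, `[[`, keys[[i]])))
    }
    out
  } else {
    do.call(f, trees)
  }
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_tree(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- map_tree(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- map_tree(
    function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}

validation_loss <- function(model, x3, y, epsilon, branched, chunk = 2048L) {
  n <- dim(x3)[1]
  acc <- 0
  per <- rep(0, ncol(y))
  for (at in seq(1L, n, by = chunk)) {
    idx <- at:min(at + chunk - 1L, n)
    X3 <- x3[idx, , , drop = FALSE]
    fw <- model_forward_tfirst(model, X3)
    lg <- mape_loss_grad(y[idx, , drop = FALSE], fw$yhat, epsilon, branched)
    per <- per + lg$per_output * length(idx)
    acc <- acc + lg$total * length(idx)
  }
  list(total = acc / n, per_output = per / n)
}

# Forward variant taking pre-transposed (batch, features, timesteps) input.
model_forward_tfirst <- function(model, X3, cache = FALSE) {
  x <- aperm(X3, c(1, 3, 2))
  model_forward(model, x, cache = cache)
}

#' Train a motion-estimation model
#'
#' Optimizes the MAPE loss with Adam. Branched models carry one loss per
#' output head and the gradient uses their unweighted sum; unbranched
#' models average a single loss across outputs. The learning rate is
#' multiplied by `lr_decay_factor` whenever the validation loss has not
#' improved for `lr_patience` consecutive epochs, and training halts after
#' `early_stop_patience` epochs without improvement. The parameters with
#' the best recorded validation loss are restored at the end. Runs are
#' reproducible given `config$seed` (bitwise under single-threaded BLAS;
#' multi-threaded builds reproduce up to floating-point reduction order).
#'
#' @param model A `motion_model` from [build_model()].
#' @param train_data,validation_data `windowed_dataset`s (normalized with
#'   training statistics).
#' @param config A [training_config()].
#' @param verbose Print one line per epoch.
#' @return A `motion_model_fit`: the trained model, a per-epoch history
#'   tibble, the config, and the best/stopped epoch indices.
#' @export
train <- function(model, train_data, validation_data, config = training_config(),
                  verbose = FALSE) {
  spec <- model$spec
  x <- train_data$x
  y <- train_data$y
  if (dim(x)[2] != spec$window || dim(x)[3] != spec$n_inputs) {
    abort_shape("training data shape does not match the model spec")
  }
  branched <- spec$topology == "branched"
  stats_hash <- attr(train_data, "stats_hash")

  x3 <- to_tfirst(x)
  xv3 <- to_tfirst(validation_data$x)
  yv <- validation_data$y
  n <- dim(x3)[1]

  params <- model$params
  state <- list(
    t = 0L,
    m = map_tree(function(p) p * 0, params),
    v = map_tree(function(p) p * 0, params)
  )
  lr <- config$initial_lr
  best <- Inf
  best_params <- params
  best_epoch <- 0L
  since_improve <- 0L
  since_decay <- 0L
  history <- vector("list", config$max_epochs)
  stopped_epoch <- config$max_epochs

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tr_acc <- 0
      tr_per <- rep(0, ncol(y))
      for (at in seq(1L, n, by = config$batch_size)) {
        idx <- ord[at:min(at + config$batch_size - 1L, n)]
        model$params <- params
        fw <- model_forward_tfirst(model, x3[idx, , , drop = FALSE], cache = TRUE)
        lg <- mape_loss_grad(y[idx, , drop = FALSE], fw$yhat,
                             config$loss_guard_epsilon, branched)
        if (!is.finite(lg$total)) {
          abort_numeric(sprintf(
            "non-finite training loss at epoch %d, batch starting at %d", epoch, at
          ))
        }
        tr_acc <- tr_acc + lg$total * length(idx)
        tr_per <- tr_per + lg$per_output * length(idx)
        grads <- model_backward(model, fw, lg$grad)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      model$params <- params
      vl <- validation_loss(model, xv3, yv, config$loss_guard_epsilon, branched)
      if (!is.finite(vl$total)) {
        abort_numeric(sprintf("non-finite validation loss at epoch %d", epoch))
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        loss = tr_acc / n,
        loss_y1 = tr_per[1] / n, loss_y2 = tr_per[2] / n,
        val_loss = vl$total,
        val_loss_y1 = vl$per_output[1], val_loss_y2 = vl$per_output[2],
        lr = lr
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2e",
                        epoch, tr_acc / n, vl$total, lr))
      }
      if (vl$total < best) {
        best <- vl$total
        best_params <- params
        best_epoch <- epoch
        since_improve <- 0L
        since_decay <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_decay <- since_decay + 1L
      }
      if (since_improve >= config$early_stop_patience) {
        stopped_epoch <- epoch
        break
      }
      if (since_decay >= config$lr_patience) {
        lr <- lr * config$lr_decay_factor
        since_decay <- 0L
      }
      stopped_epoch <- epoch
    }
  })

  model$params <- best_params
  structure(
    list(
      model = model,
      history = dplyr::bind_rows(history),
      config = config,
      best_epoch = best_epoch,
      stopped_epoch = stopped_epoch,
      best_val_loss = best,
      stats_hash = stats_hash
    ),
    class = "motion_model_fit"
  )
}

#' @export
print.motion_model_fit <- function(x, ...) {
  print(x$model$spec)
  cat(sprintf(
    "  trained %d epoch(s); best validation loss %.4f at epoch %d\n",
    x$stopped_epoch, x$best_val_loss, x$best_epoch
  ))
  invisible(x)
}
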