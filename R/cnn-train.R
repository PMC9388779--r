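#' Training configuration for the 3D CNN
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience_epochs Early-stopping patience (must be < `max_epochs`).
#' @param batch_size Minibatch size.
#' @param min_improve Relative improvement in validation error below which
#'   an epoch counts as "not decreasing" (strict float comparison is
#'   seed-fragile).
#' @param seed RNG seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 1000L,
                         patience_epochs = 100L, batch_size = 8L,
                         min_improve = 1e-6, seed = 1L) {
  if (patience_epochs >= max_epochs)
    stopf("patience_epochs must be smaller than max_epochs")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 batch_size = as.integer(batch_size),
                 min_improve = min_improve, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(model) {
  list(m = zero_grads(model), v = zero_grads(model), t = 0L)
}

# one Adam update; conv blocks listed in `frozen` are skipped entirely
adam_step <- function(model, grads, state, lr, frozen = integer(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(path_get, path_set) {
    g <- path_get(grads)
    m <- beta1 * path_get(state$m) + (1 - beta1) * g
    v <- beta2 * path_get(state$v) + (1 - beta2) * g^2
    state$m <<- path_set(state$m, m)
    state$v <<- path_set(state$v, v)
    p <- path_get(model$params) -
      lr * (m / corr1) / (sqrt(v / corr2) + eps)
    model$params <<- path_set(model$params, p)
  }
  for (b in seq_along(model$params$conv)) {
    if (b %in% frozen) next
    upd(function(x) x$conv[[b]]$W,
        function(x, v) { x$conv[[b]]$W <- v; x })
    upd(function(x) x$conv[[b]]$b,
        function(x, v) { x$conv[[b]]$b <- v; x })
  }
  for (nm in c("fc1", "fc2")) {
    upd(function(x) x[[nm]]$W, function(x, v) { x[[nm]]$W <- v; x })
    upd(function(x) x[[nm]]$b, function(x, v) { x[[nm]]$b <- v; x })
  }
  list(model = model, state = state)
}

#' Train a 3D CNN with revert-style early stopping
#'
#' Trains with minibatch Adam on the cross-entropy loss. After every epoch
#' the validation error is computed (mean cross-entropy on `val_xs`, or a
#' caller-supplied `eval_fn`). When the best validation error has not
#' improved by at least `min_improve` (relative) for `patience_epochs`
#' consecutive epochs, the training state is reverted to the checkpoint of
#' the first epoch of that non-improving span and training stops; otherwise
#' training runs to `max_epochs`.
#'
#' @param model A [build_cnn()] model.
#' @param xs,ys Training volumes (list of 3D arrays) and 0/1 labels.
#' @param config A [train_config()].
#' @param val_xs,val_ys Optional validation split for early stopping.
#' @param eval_fn Optional `function(model, epoch)` returning the
#'   validation error (overrides `val_xs`; used e.g. to script error
#'   sequences in tests).
#' @param frozen Integer indices of conv blocks excluded from updates.
#' @return A list with `model`, `history` (data.frame: epoch, train_loss,
#'   val_error, checksum_sum, checksum_sumsq), `reverted` and `revert_to`
#'   (the restored epoch, or `NA`).
#' @export
train_with_revert <- function(model, xs, ys, config = train_config(),
                              val_xs = NULL, val_ys = NULL, eval_fn = NULL,
                              frozen = integer(0)) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  has_val <- !is.null(eval_fn) || !is.null(val_xs)
  state <- adam_init(model)
  patience <- config$patience_epochs
  ring <- vector("list", patience)               # last `patience` checkpoints
  history <- vector("list", config$max_epochs)
  best <- Inf
  since_improve <- 0L
  reverted <- FALSE
  revert_to <- NA_integer_

  with_seed(config$seed, {
    n <- length(xs)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        lg <- cnn_loss_grad(model, xs[idx], ys[idx], training = TRUE)
        if (!is.finite(lg$loss))
          stopf("non-finite training loss at epoch %d", epoch)
        res <- adam_step(model, lg$grads, state, config$learning_rate,
                         frozen = frozen)
        model <- res$model
        state <- res$state
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1
      }
      val_err <- if (!is.null(eval_fn)) eval_fn(model, epoch)
        else if (has_val) cnn_eval_loss(model, val_xs, val_ys)
        else NA_real_
      ring[[(epoch - 1L) %% patience + 1L]] <-
        list(epoch = epoch, params = model$params)
      ck <- param_checksum(model)
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                     val_error = val_err,
                                     checksum_sum = ck[1],
                                     checksum_sumsq = ck[2])
      if (has_val) {
        improved <- (best - val_err) >= config$min_improve * max(abs(best), 1)
        if (!is.finite(best)) improved <- is.finite(val_err)
        if (improved) {
          best <- val_err
          since_improve <- 0L
        } else {
          since_improve <- since_improve + 1L
        }
        if (since_improve >= patience) {
          revert_to <- epoch - patience + 1L
          ckpt <- ring[[(revert_to - 1L) %% patience + 1L]]
          stopifnot(ckpt$epoch == revert_to)
          model$params <- ckpt$params
          reverted <- TRUE
          break
        }
      }
    }
  })
  list(model = model, history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
       reverted = reverted, revert_to = revert_to)
}

#' Transfer learning: freeze early layers and fine-tune
#'
#' Freezes the parameters of the first `n_frozen_layers` convolution blocks
#' of a pre-trained model, re-initializes the decision layers (seeded), and
#' continues training on the target data. Frozen parameters are bit
#' identical before and after fine-tuning.
#'
#' @param pretrained A trained [build_cnn()] model.
#' @param xs,ys Target training data.
#' @param n_frozen_layers Number of leading conv blocks to freeze.
#' @param config A [train_config()].
#' @param val_xs,val_ys,eval_fn Passed to [train_with_revert()].
#' @return As [train_with_revert()], plus `frozen` (the frozen block
#'   indices).
#' @export
transfer_finetune <- function(pretrained, xs, ys, n_frozen_layers = 4,
                              config = train_config(), val_xs = NULL,
                              val_ys = NULL, eval_fn = NULL) {
  stopifnot(inherits(pretrained, "cnn_model"))
  nb <- length(pretrained$arch$blocks)
  if (n_frozen_layers > nb)
    stopf("n_frozen_layers (%d) exceeds the %d feature-extraction blocks",
          n_frozen_layers, nb)
  model <- pretrained
  arch <- model$arch
  # fresh, seeded decision layers; feature-extraction stack is carried over
  with_seed(config$seed, {
    model$params$fc1 <- list(
      W = matrix(stats::rnorm(arch$flat_dim * arch$fc_units,
                              sd = sqrt(2 / arch$flat_dim)),
                 arch$flat_dim, arch$fc_units),
      b = rep(0, arch$fc_units))
    model$params$fc2 <- list(
      W = matrix(stats::rnorm(arch$fc_units * 2, sd = sqrt(2 / arch$fc_units)),
                 arch$fc_units, 2),
      b = rep(0, 2))
  })
  frozen <- seq_len(n_frozen_layers)
  out <- train_with_revert(model, xs, ys, config, val_xs = val_xs,
                           val_ys = val_ys, eval_fn = eval_fn,
                           frozen = frozen)
  out$frozen <- frozen
  out
}
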