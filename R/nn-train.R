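# Shared training machinery: AdamW, minibatching, validation-based early
# stopping with best-epoch restoration, and reduce-on-plateau learning-rate
# scheduling. Every model in the package (autoencoder, classifier head,
# adaptation stages, neural baselines) trains through this one loop, so the
# freeze semantics and callbacks are identical everywhere.

#' Training configuration
#'
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs (0 performs no training).
#' @param learning_rate Initial AdamW learning rate.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping; the best-validation parameters are restored on exit.
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor Multiplicative learning-rate reduction in `(0, 1)`.
#' @param min_lr Learning-rate floor for the scheduler.
#' @param seed Seed for minibatch shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 64L, max_epochs = 40L, learning_rate = 1e-3,
                         weight_decay = 1e-4, early_stop_patience = 10L,
                         plateau_patience = 5L, plateau_factor = 0.5,
                         min_lr = 1e-5, seed = 1L) {
  stopifnot(batch_size >= 1L, max_epochs >= 0L, learning_rate > 0,
            weight_decay >= 0, early_stop_patience >= 1L, plateau_patience >= 1L,
            plateau_factor > 0, plateau_factor < 1, min_lr > 0)
  structure(
    list(batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate, weight_decay = weight_decay,
         early_stop_patience = as.integer(early_stop_patience),
         plateau_patience = as.integer(plateau_patience),
         plateau_factor = plateau_factor, min_lr = min_lr, seed = as.integer(seed)),
    class = "train_config"
  )
}

adamw_init <- function(params, trainable) {
  list(
    m = lapply(params[trainable], function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params[trainable], function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adamw_step <- function(params, grads, state, trainable, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * as.numeric(g)
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * as.numeric(g)^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    p_dim <- dim(params[[nm]])
    p_new <- as.numeric(params[[nm]]) - lr * (upd + wd * as.numeric(params[[nm]]))
    dim(p_new) <- p_dim
    params[[nm]] <- p_new
  }
  list(params = params, state = state)
}

# Generic fitting loop.
#   step_fn(params, idx)  -> list(loss, grads) on training indices idx
#   val_fn(params)        -> scalar validation loss (lower is better)
fit_network <- function(params, n_train, step_fn, val_fn, tc, trainable = NULL) {
  if (is.null(trainable)) trainable <- names(params)
  history <- list(train_loss = numeric(0), val_loss = numeric(0), lr = numeric(0))
  if (tc$max_epochs == 0L || length(trainable) == 0L) {
    history$stopped_epoch <- 0L; history$best_epoch <- 0L
    return(list(params = params, history = history))
  }
  state <- adamw_init(params, trainable)
  lr <- tc$learning_rate
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait_stop <- 0L
  wait_plateau <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- with_seed(substream_seed(tc$seed, paste0("epoch:", epoch)),
                     sample.int(n_train))
    ep_loss <- 0; n_b <- 0L
    for (start in seq(1L, n_train, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n_train)]
      r <- step_fn(params, idx)
      if (!is.finite(r$loss)) {
        stop(sprintf("training diverged at epoch %d (loss = %g)", epoch, r$loss),
             call. = FALSE)
      }
      st <- adamw_step(params, r$grads, state, trainable, lr, tc$weight_decay)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + r$loss; n_b <- n_b + 1L
    }
    vl <- val_fn(params)
    history$train_loss <- c(history$train_loss, ep_loss / n_b)
    history$val_loss <- c(history$val_loss, vl)
    history$lr <- c(history$lr, lr)
    if (vl < best_val - 1e-9) {
      best_val <- vl; best_params <- params; best_epoch <- epoch
      wait_stop <- 0L; wait_plateau <- 0L
    } else {
      wait_stop <- wait_stop + 1L
      wait_plateau <- wait_plateau + 1L
      if (wait_plateau >= tc$plateau_patience && lr > tc$min_lr) {
        lr <- max(lr * tc$plateau_factor, tc$min_lr)
        wait_plateau <- 0L
      }
      if (wait_stop >= tc$early_stop_patience) break
    }
  }
  history$stopped_epoch <- length(history$train_loss)
  history$best_epoch <- best_epoch
  list(params = best_params, history = history)
}
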