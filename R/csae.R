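# Convolutional sparse autoencoder --------------------------------------------

#' Leaky rectified linear unit
#'
#' `x` for positive inputs, `alpha * x` otherwise. The small negative slope
#' keeps a nonzero gradient for inactive units, avoiding "dying ReLU".
#'
#' @param x Numeric scalar or array.
#' @param alpha Nonnegative negative-branch slope.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, alpha = 0.01) {
  stopifnot(alpha >= 0)
  ifelse(x > 0, x, alpha * x)
}

#' L1 activity (sparsity) penalty on latent activations
#'
#' `lambda * sum(|Z|) / N`, where the sum runs over every activation in the
#' batch and `N` is the batch size (first array dimension; 1 for a plain
#' vector or matrix treated as a single sample). Dividing by the batch size
#' keeps the meaning of `lambda` invariant to batch size; the identical
#' reduction is used inside the composite training loss.
#'
#' @param z Latent activations: vector, matrix (one sample) or N x T' x D array.
#' @param lambda Nonnegative regularization coefficient.
#' @return Scalar penalty.
#' @export
sparsity_penalty <- function(z, lambda) {
  stopifnot(lambda >= 0)
  n <- if (length(dim(z)) == 3L) dim(z)[1L] else 1L
  lambda * sum(abs(z)) / n
}

#' Composite autoencoder loss
#'
#' Mean squared reconstruction error (mean over every element of the batch)
#' plus the L1 activity penalty of [sparsity_penalty()]. The decomposition
#' `csae_loss(x, xhat, z, lambda) == csae_loss(x, xhat, z, 0) +
#' sparsity_penalty(z, lambda)` holds exactly.
#'
#' @param x Input batch.
#' @param xhat Reconstruction, same shape as `x`.
#' @param z Latent activations.
#' @param lambda L1 coefficient.
#' @return Scalar loss.
#' @export
csae_loss <- function(x, xhat, z, lambda) {
  if (!identical(dim(x), dim(xhat))) {
    stop("`x` and `xhat` must have identical shapes", call. = FALSE)
  }
  mean((x - xhat)^2) + sparsity_penalty(z, lambda)
}

#' Autoencoder architecture configuration
#'
#' The temporal compression is `enc_strides[1] * enc_strides[2]`; the segment
#' length must divide by it, and each kernel must be at least as long as its
#' stride. Defaults give `T' = 50` for the 1000-sample (250 ms at 4 kHz)
#' segments of the full-scale protocol.
#'
#' @param enc_filters Filter counts of the two downsampling conv blocks.
#' @param enc_kernels Kernel lengths of conv I, conv II, and the bottleneck.
#' @param enc_strides Strides (> 1) of the two downsampling blocks.
#' @param latent_filters Number of bottleneck filters `D`.
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param l1_coeff L1 activity-regularization coefficient on the bottleneck
#'   output (post-activation).
#' @param seed Seed for He-Normal initialization.
#' @return A `csae_config`.
#' @export
csae_config <- function(enc_filters = c(32L, 64L), enc_kernels = c(7L, 5L, 3L),
                        enc_strides = c(4L, 5L), latent_filters = 32L,
                        leaky_slope = 0.01, l1_coeff = 1e-7, seed = 1L) {
  stopifnot(length(enc_filters) == 2L, length(enc_kernels) == 3L,
            length(enc_strides) == 2L, all(enc_strides > 1L),
            latent_filters >= 1L, leaky_slope >= 0, l1_coeff >= 0)
  if (any(enc_kernels[1:2] < enc_strides)) {
    stop("each kernel must be >= its stride under the same-style padding rule",
         call. = FALSE)
  }
  structure(
    list(enc_filters = as.integer(enc_filters), enc_kernels = as.integer(enc_kernels),
         enc_strides = as.integer(enc_strides), latent_filters = as.integer(latent_filters),
         leaky_slope = leaky_slope, l1_coeff = l1_coeff, seed = as.integer(seed)),
    class = "csae_config"
  )
}

#' Build a convolutional sparse autoencoder
#'
#' Encoder: two strided 1-D convolutional blocks (learnable downsampling,
#' LeakyReLU) followed by a stride-1 bottleneck convolution emitting the
#' latent map `Z` (T' x D, T' < T). Decoder: the mirror image with
#' transposed convolutions of identical strides, closed by a linear stride-1
#' convolution restoring the T x C input shape. Weights are He-Normal
#' initialized under the config seed.
#'
#' @param config A `csae_config`.
#' @param input_shape `c(T, C)`: samples per segment and channel count.
#' @return An `semg_csae` model.
#' @export
build_csae <- function(config, input_shape) {
  stopifnot(inherits(config, "csae_config"), length(input_shape) == 2L)
  t_in <- as.integer(input_shape[1L]); c_in <- as.integer(input_shape[2L])
  s1 <- config$enc_strides[1L]; s2 <- config$enc_strides[2L]
  if (t_in %% (s1 * s2) != 0L) {
    stop(sprintf("segment length %d is not divisible by the stride product %d",
                 t_in, s1 * s2), call. = FALSE)
  }
  f <- config$enc_filters; k <- config$enc_kernels; a <- config$leaky_slope
  d_lat <- config$latent_filters
  enc <- list(
    nn_layer("enc1", "conv", k = k[1L], stride = s1, in_ch = c_in, out_ch = f[1L]),
    nn_layer("enc1a", "lrelu", alpha = a),
    nn_layer("enc2", "conv", k = k[2L], stride = s2, in_ch = f[1L], out_ch = f[2L]),
    nn_layer("enc2a", "lrelu", alpha = a),
    nn_layer("bott", "conv", k = k[3L], stride = 1L, in_ch = f[2L], out_ch = d_lat),
    nn_layer("botta", "lrelu", alpha = a)
  )
  dec <- list(
    nn_layer("dec1", "tconv", k = k[2L], stride = s2, in_ch = d_lat, out_ch = f[2L]),
    nn_layer("dec1a", "lrelu", alpha = a),
    nn_layer("dec2", "tconv", k = k[1L], stride = s1, in_ch = f[2L], out_ch = f[1L]),
    nn_layer("dec2a", "lrelu", alpha = a),
    nn_layer("recon", "conv", k = k[3L], stride = 1L, in_ch = f[1L], out_ch = c_in)
  )
  params <- c(nn_init(enc, substream_seed(config$seed, "enc")),
              nn_init(dec, substream_seed(config$seed, "dec")))
  structure(
    list(enc_layers = enc, dec_layers = dec, params = params, config = config,
         input_shape = c(t_in, c_in), latent_steps = t_in %/% (s1 * s2),
         history = NULL),
    class = "semg_csae"
  )
}

#' @export
print.semg_csae <- function(x, ...) {
  cat(sprintf(
    "<semg_csae> %d x %d -> latent %d x %d (lambda = %g, %d parameters)%s\n",
    x$input_shape[1L], x$input_shape[2L], x$latent_steps,
    x$config$latent_filters, x$config$l1_coeff,
    sum(vapply(x$params, length, integer(1))),
    if (is.null(x$history)) " [untrained]" else ""
  ))
  invisible(x)
}

as_segment_array <- function(batch) {
  if (inherits(batch, "semg_segments")) batch$segments
  else if (length(dim(batch)) == 3L) batch
  else stop("expected an `semg_segments` or an N x T x C array", call. = FALSE)
}

#' Encode segments into the latent feature map
#'
#' Deterministic forward pass of the encoder only.
#'
#' @param model An `semg_csae`.
#' @param batch `semg_segments` or N x T x C array (standardized).
#' @return N x T' x D latent array.
#' @export
encode <- function(model, batch) {
  stopifnot(inherits(model, "semg_csae"))
  x <- as_segment_array(batch)
  check_input_shape(model$input_shape, x)
  nn_forward(model$enc_layers, model$params, x, keep_cache = FALSE)$out
}

#' Decode latent features back to the signal domain
#'
#' @param model An `semg_csae`.
#' @param z N x T' x D latent array.
#' @return N x T x C reconstruction.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "semg_csae"), length(dim(z)) == 3L)
  nn_forward(model$dec_layers, model$params, z, keep_cache = FALSE)$out
}

check_input_shape <- function(shape, x) {
  d <- dim(x)
  if (d[2L] != shape[1L] || d[3L] != shape[2L]) {
    stop(sprintf("input shape %d x %d does not match the model's %d x %d",
                 d[2L], d[3L], shape[1L], shape[2L]), call. = FALSE)
  }
  invisible(TRUE)
}

csae_batch_grad <- function(model, x) {
  lam <- model$config$l1_coeff
  n <- dim(x)[1L]
  fe <- nn_forward(model$enc_layers, model$params, x)
  z <- fe$out
  fd <- nn_forward(model$dec_layers, model$params, z)
  xhat <- fd$out
  loss <- mean((x - xhat)^2) + lam * sum(abs(z)) / n
  dxhat <- 2 * (xhat - x) / length(x)
  bd <- nn_backward(model$dec_layers, model$params, fd$caches, dxhat)
  dz <- bd$dx + lam * sign(z) / n
  be <- nn_backward(model$enc_layers, model$params, fe$caches, dz)
  list(loss = loss, grads = c(be$grads, bd$grads))
}

#' Train the autoencoder (unsupervised)
#'
#' Minimizes the composite loss of [csae_loss()] with AdamW, minibatch
#' shuffling, reduce-on-plateau learning-rate scheduling, and early stopping
#' on the validation loss; the best-validation parameters are restored on
#' exit. Inputs must already be standardized with the training-partition
#' scaler, and `val` must be disjoint from `train` by trial.
#'
#' @param model An `semg_csae` from [build_csae()].
#' @param train,val `semg_segments` (or arrays) for training and validation.
#' @param tc A [train_config()].
#' @return The trained `semg_csae` with `$history` filled in.
#' @export
train_csae <- function(model, train, val, tc = train_config()) {
  stopifnot(inherits(model, "semg_csae"))
  x_tr <- as_segment_array(train)
  x_va <- as_segment_array(val)
  check_input_shape(model$input_shape, x_tr)
  check_input_shape(model$input_shape, x_va)
  lam <- model$config$l1_coeff
  step_fn <- function(params, idx) {
    m <- model; m$params <- params
    csae_batch_grad(m, x_tr[idx, , , drop = FALSE])
  }
  val_fn <- function(params) {
    m <- model; m$params <- params
    z <- nn_forward(m$enc_layers, params, x_va, keep_cache = FALSE)$out
    xhat <- nn_forward(m$dec_layers, params, z, keep_cache = FALSE)$out
    mean((x_va - xhat)^2) + lam * sum(abs(z)) / dim(x_va)[1L]
  }
  fit <- fit_network(model$params, dim(x_tr)[1L], step_fn, val_fn, tc)
  model$params <- fit$params
  model$history <- fit$history
  model
}

#' Reconstruction R-squared
#'
#' Coefficient of determination pooled over every element of the batch:
#' `1 - SSE / SST`, with SST taken about the pooled batch mean. 1 means a
#' perfect reconstruction; 0 is the score of predicting the batch mean
#' everywhere.
#'
#' @param model A trained `semg_csae`.
#' @param batch `semg_segments` or array (standardized like the training data).
#' @return Scalar R-squared.
#' @export
r2_reconstruction <- function(model, batch) {
  x <- as_segment_array(batch)
  sst <- sum((x - mean(x))^2)
  if (sst == 0) stop("batch has zero variance; R-squared is undefined", call. = FALSE)
  xhat <- decode(model, encode(model, x))
  1 - sum((x - xhat)^2) / sst
}

#' Fraction of near-zero latent activations
#'
#' Summary of bottleneck sparsity: the proportion of latent activations with
#' absolute value below `thresh` on the given batch.
#'
#' @param model A trained `semg_csae`.
#' @param batch `semg_segments` or array.
#' @param thresh Magnitude below which an activation counts as inactive.
#' @return Fraction in `[0, 1]`.
#' @export
latent_sparsity <- function(model, batch, thresh = 1e-3) {
  z <- encode(model, batch)
  mean(abs(z) < thresh)
}
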