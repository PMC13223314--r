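# Attention-pooled classifier head over frozen encoder features ---------------

#' Classifier head configuration
#'
#' @param head_conv_filters,head_conv_kernel Temporal convolution over the
#'   latent sequence (stride 1).
#' @param attention_dim Hidden width of the additive attention scorer.
#' @param mlp_dims Widths of the two MLP stages.
#' @param n_classes Number of movement classes `K` (>= 2).
#' @param leaky_slope LeakyReLU negative slope reused throughout the head.
#' @param seed Seed for He-Normal head initialization.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(head_conv_filters = 64L, head_conv_kernel = 3L,
                              attention_dim = 32L, mlp_dims = c(128L, 64L),
                              n_classes = 6L, leaky_slope = 0.01, seed = 1L) {
  stopifnot(length(mlp_dims) == 2L, head_conv_filters >= 1L,
            head_conv_kernel >= 1L, attention_dim >= 1L)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  structure(
    list(head_conv_filters = as.integer(head_conv_filters),
         head_conv_kernel = as.integer(head_conv_kernel),
         attention_dim = as.integer(attention_dim),
         mlp_dims = as.integer(mlp_dims), n_classes = as.integer(n_classes),
         leaky_slope = leaky_slope, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

head_layer_graph <- function(d_latent, config, n_classes) {
  a <- config$leaky_slope
  list(
    nn_layer("ln", "featnorm", dim = d_latent),
    nn_layer("hconv", "conv", k = config$head_conv_kernel, stride = 1L,
             in_ch = d_latent, out_ch = config$head_conv_filters),
    nn_layer("hconva", "lrelu", alpha = a),
    nn_layer("attn", "attnpool", dim = config$head_conv_filters,
             attn_dim = config$attention_dim),
    nn_layer("mlp1", "dense", n_in = config$head_conv_filters,
             n_out = config$mlp_dims[1L]),
    nn_layer("mlp1a", "lrelu", alpha = a),
    nn_layer("mlp2", "dense", n_in = config$mlp_dims[1L],
             n_out = config$mlp_dims[2L]),
    nn_layer("mlp2a", "lrelu", alpha = a),
    nn_layer("out", "dense", n_in = config$mlp_dims[2L], n_out = n_classes)
  )
}

#' Build the movement classifier on a frozen encoder
#'
#' Architecture: frozen CSAE encoder; a feature-normalization layer that
#' z-scores every latent filter with statistics fitted on the training-set
#' latents (frozen at inference, learned per-filter affine on top) to damp
#' inter-trial and inter-subject variance; one stride-1 temporal convolution
#' with LeakyReLU; additive self-attention pooling into a context vector; a
#' two-stage MLP; and a softmax output over the ordered class list. Encoder
#' parameters are copied into the classifier and never updated by any
#' training entry point in this package.
#'
#' @param encoder A (typically trained) `semg_csae`.
#' @param config A `classifier_config`.
#' @param class_list Ordered character vector of gesture ids; its length must
#'   equal `config$n_classes`. Output column j corresponds to
#'   `class_list[j]`.
#' @return An `semg_classifier`.
#' @export
build_classifier <- function(encoder, config, class_list) {
  stopifnot(inherits(encoder, "semg_csae"), inherits(config, "classifier_config"))
  class_list <- as.character(class_list)
  if (length(class_list) != config$n_classes) {
    stop("`class_list` length must equal `config$n_classes`", call. = FALSE)
  }
  if (anyDuplicated(class_list)) stop("`class_list` has duplicates", call. = FALSE)
  d_lat <- encoder$config$latent_filters
  head_layers <- head_layer_graph(d_lat, config, config$n_classes)
  head_params <- nn_init(head_layers, substream_seed(config$seed, "head"))
  enc_names <- unlist(lapply(encoder$enc_layers, function(ly) {
    grep(paste0("^", ly$name, "_"), names(encoder$params), value = TRUE)
  }))
  structure(
    list(
      enc_layers = encoder$enc_layers,
      enc_params = encoder$params[enc_names],
      head_layers = head_layers,
      head_params = head_params,
      config = config,
      class_list = class_list,
      input_shape = encoder$input_shape,
      history = NULL
    ),
    class = "semg_classifier"
  )
}

#' @export
print.semg_classifier <- function(x, ...) {
  cat(sprintf(
    "<semg_classifier> %d classes (%s), frozen encoder + %d head parameters%s\n",
    x$config$n_classes, paste(x$class_list, collapse = ", "),
    sum(vapply(x$head_params, length, integer(1))),
    if (is.null(x$history)) " [untrained]" else ""
  ))
  invisible(x)
}

#' Named parameter groups of the classifier head
#'
#' Used by the freeze plans of the adaptation protocols: `layer_norm`,
#' `conv`, `attention`, `mlp_fc` (both MLP stages), `output_softmax`.
#'
#' @param model An `semg_classifier`.
#' @return Named list of head-parameter-name character vectors.
#' @export
classifier_param_groups <- function(model) {
  nm <- names(model$head_params)
  list(
    layer_norm = grep("^ln_(g|b)$", nm, value = TRUE),
    conv = grep("^hconv", nm, value = TRUE),
    attention = grep("^attn_", nm, value = TRUE),
    mlp_fc = grep("^mlp", nm, value = TRUE),
    output_softmax = grep("^out_", nm, value = TRUE)
  )
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

#' Categorical cross-entropy
#'
#' Mean over the batch of `-sum_i y'_i log(p_i)`; probabilities are clamped
#' at `eps` so a zero probability at the true class stays finite.
#'
#' @param p_hat N x K row-stochastic predicted probabilities.
#' @param y_onehot N x K one-hot truth.
#' @param eps Probability clamp.
#' @return Scalar loss.
#' @export
cross_entropy <- function(p_hat, y_onehot, eps = 1e-12) {
  stopifnot(identical(dim(p_hat), dim(y_onehot)))
  -mean(rowSums(y_onehot * log(pmax(p_hat, eps))))
}

#' Attention pooling of a feature sequence
#'
#' Scores each time step with an additive scorer `e_t = v' tanh(W h_t + b)`,
#' converts scores to weights with a softmax over time, and returns the
#' weighted context vector together with the weights for introspection.
#'
#' @param h T x D matrix (one sequence) or N x T x D array.
#' @param w,b,v Scorer parameters: `w` D x A, `b` length A, `v` length A.
#' @return List with `context` (D vector or N x D matrix) and `weights`
#'   (T vector or N x T matrix, nonnegative, summing to 1 per sequence).
#' @export
attention_pool <- function(h, w, b, v) {
  single <- length(dim(h)) == 2L
  if (single) h <- array(h, dim = c(1L, nrow(h), ncol(h)))
  r <- attnpool_fwd(h, w, b, v)
  if (single) list(context = as.numeric(r$y), weights = as.numeric(r$weights))
  else list(context = r$y, weights = r$weights)
}

classifier_forward_head <- function(model, z, keep_cache = FALSE) {
  nn_forward(model$head_layers, model$head_params, z, keep_cache = keep_cache)
}

# frozen normalization buffers (never optimized; set once from training
# latents, then reused unchanged for target-subject and expanded-class data,
# mirroring the treatment of the input scaler)
head_buffer_names <- function(model) {
  grep("_(mu|sigma)$", names(model$head_params), value = TRUE)
}

# fit the feature-normalization buffers on training latents (only while they
# are still at their build-time defaults, so adaptation stages reuse the
# source-domain statistics)
fit_featnorm_buffers <- function(model, z_tr, eps = 1e-8) {
  if (!identical(as.numeric(model$head_params$ln_mu),
                 rep(0, length(model$head_params$ln_mu)))) {
    return(model)
  }
  d <- dim(z_tr)
  zm <- z_tr
  dim(zm) <- c(d[1L] * d[2L], d[3L])
  model$head_params$ln_mu <- colMeans(zm)
  model$head_params$ln_sigma <- pmax(apply(zm, 2L, stats::sd), eps)
  model
}

#' Predict movement probabilities
#'
#' Deterministic inference: frozen encoder, head, softmax. Argmax ties are
#' broken toward the lowest class index.
#'
#' @param object An `semg_classifier`.
#' @param batch `semg_segments` or standardized N x T x C array.
#' @param ... Unused.
#' @return List with `prob` (N x K, rows sum to 1), `labels` (character),
#'   and `attention` (N x T' attention weights).
#' @export
predict.semg_classifier <- function(object, batch, ...) {
  x <- as_segment_array(batch)
  check_input_shape(object$input_shape, x)
  z <- nn_forward(object$enc_layers, object$enc_params, x, keep_cache = FALSE)$out
  fw <- classifier_forward_head(object, z)
  prob <- softmax_rows(fw$out)
  colnames(prob) <- object$class_list
  list(
    prob = prob,
    labels = object$class_list[max.col(prob, ties.method = "first")],
    attention = fw$extras$attn
  )
}

# Shared supervised trainer over precomputed latents; trainable selects head
# parameter names (the encoder is excluded by construction).
train_head <- function(model, z_tr, y_tr, z_va, y_va, tc, trainable = NULL) {
  if (is.null(trainable)) trainable <- setdiff(names(model$head_params),
                                               head_buffer_names(model))
  step_fn <- function(params, idx) {
    m <- model; m$head_params <- params
    fw <- nn_forward(m$head_layers, params, z_tr[idx, , , drop = FALSE], keep_cache = TRUE)
    p <- softmax_rows(fw$out)
    yb <- y_tr[idx, , drop = FALSE]
    loss <- cross_entropy(p, yb)
    dlogits <- (p - yb) / nrow(yb)
    bw <- nn_backward(m$head_layers, params, fw$caches, dlogits)
    list(loss = loss, grads = bw$grads)
  }
  val_fn <- function(params) {
    fw <- nn_forward(model$head_layers, params, z_va, keep_cache = FALSE)
    cross_entropy(softmax_rows(fw$out), y_va)
  }
  fit <- fit_network(model$head_params, dim(z_tr)[1L], step_fn, val_fn, tc,
                     trainable = trainable)
  model$head_params <- fit$params
  model$history <- fit$history
  model
}

encode_with <- function(model, batch) {
  x <- as_segment_array(batch)
  check_input_shape(model$input_shape, x)
  nn_forward(model$enc_layers, model$enc_params, x, keep_cache = FALSE)$out
}

check_labels <- function(labels, class_list) {
  bad <- setdiff(unique(labels), class_list)
  if (length(bad) > 0L) {
    stop(sprintf("label(s) outside the model's class list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Train the classifier head (encoder frozen)
#'
#' Minimizes categorical cross-entropy over the head parameters only, with
#' the same AdamW / early-stopping / plateau-scheduler machinery as the
#' autoencoder. Because the encoder is frozen, latent features are
#' precomputed once per partition.
#'
#' @param model An `semg_classifier`.
#' @param train,val Standardized `semg_segments` with labels.
#' @param tc A [train_config()].
#' @param n_restarts Number of head initializations to train; the run with
#'   the lowest validation loss is kept. Restart seeds derive from the head
#'   config seed, so the procedure is deterministic. Restarting a small head
#'   is cheap and damps initialization variance.
#' @return The trained `semg_classifier`.
#' @export
train_classifier <- function(model, train, val, tc = train_config(), n_restarts = 1L) {
  stopifnot(inherits(model, "semg_classifier"), inherits(train, "semg_segments"),
            n_restarts >= 1L)
  check_labels(train$labels, model$class_list)
  check_labels(val$labels, model$class_list)
  present <- model$class_list %in% train$labels
  if (sum(present) < 2L) {
    stop("training data must contain at least one sample for >= 2 classes", call. = FALSE)
  }
  z_tr <- encode_with(model, train)
  z_va <- encode_with(model, val)
  model <- fit_featnorm_buffers(model, z_tr)
  y_tr <- one_hot(train$labels, model$class_list)
  y_va <- one_hot(val$labels, model$class_list)
  best <- NULL
  best_val <- Inf
  for (r in seq_len(n_restarts)) {
    cand <- model
    if (r > 1L) {
      cand$head_params <- nn_init(
        cand$head_layers, substream_seed(model$config$seed, paste0("restart:", r)))
      tc_r <- tc; tc_r$seed <- substream_seed(tc$seed, paste0("restart:", r))
    } else tc_r <- tc
    cand <- train_head(cand, z_tr, y_tr, z_va, y_va, tc_r)
    vl <- if (length(cand$history$val_loss) > 0L) min(cand$history$val_loss) else {
      fw <- nn_forward(cand$head_layers, cand$head_params, z_va, keep_cache = FALSE)
      cross_entropy(softmax_rows(fw$out), y_va)
    }
    if (vl < best_val) { best_val <- vl; best <- cand }
  }
  best
}
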