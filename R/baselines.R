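# Benchmark pipelines and model cost accounting -------------------------------

#' Classical time-domain features
#'
#' The fixed per-channel feature set (Hudgins-style): mean absolute value,
#' variance, zero-crossing count, waveform length, slope-sign-change count,
#' and root mean square. The zero-crossing / slope-sign thresholds are 0,
#' appropriate for standardized (zero-mean) signals.
#'
#' @param x A T x C segment matrix, an N x T x C array, or `semg_segments`.
#' @return A named feature vector (single segment) or N x (6 C) matrix.
#' @export
classical_features <- function(x) {
  if (inherits(x, "semg_segments") || length(dim(x)) == 3L) {
    arr <- as_segment_array(x)
    out <- t(apply(arr, 1L, function(m) classical_features(matrix(m, dim(arr)[2L], dim(arr)[3L]))))
    colnames(out) <- names(classical_features(matrix(arr[1L, , ], dim(arr)[2L], dim(arr)[3L])))
    return(out)
  }
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L)
  feats <- lapply(seq_len(ncol(x)), function(ci) {
    v <- x[, ci]
    d <- diff(v)
    c(
      mav = mean(abs(v)),
      var = stats::var(v),
      zc = sum(v[-1L] * v[-length(v)] < 0),
      wl = sum(abs(d)),
      ssc = sum(d[-1L] * d[-length(d)] < 0),
      rms = sqrt(mean(v^2))
    )
  })
  out <- unlist(feats)
  names(out) <- paste0(rep(paste0("ch", seq_len(ncol(x))), each = 6L), "_",
                       names(feats[[1L]]))
  out
}

#' Random-forest classifier over flat feature vectors
#'
#' Standard random forest (500 trees by default) with a fixed seed for
#' reproducible predictions. Used with [classical_features()] and with FCAE
#' bottleneck features.
#'
#' @param features N x F numeric matrix.
#' @param labels Character labels, length N.
#' @param ntree Number of trees.
#' @param seed Seed for forest construction.
#' @return An `semg_rf` wrapper with a `predict` method returning labels.
#' @export
train_rf_baseline <- function(features, labels, ntree = 500L, seed = 1L) {
  y <- factor(labels)
  fit <- with_seed(seed, randomForest::randomForest(x = features, y = y, ntree = ntree))
  structure(list(fit = fit, class_list = levels(y)), class = "semg_rf")
}

#' @export
predict.semg_rf <- function(object, features, ...) {
  as.character(stats::predict(object$fit, features))
}

# Fully-connected autoencoder baseline ----------------------------------------

#' Build a fully-connected autoencoder over flattened segments
#'
#' The input (T, C) segment is flattened into a length T*C vector, which
#' discards the temporal ordering from the architecture's point of view: a
#' dense layer is equivariant to any fixed permutation of its inputs. The
#' encoder is `hidden[1] -> hidden[2] -> bottleneck` with LeakyReLU, the
#' decoder mirrors it, and training minimizes plain MSE (no sparsity
#' penalty) through the shared machinery.
#'
#' @param input_shape `c(T, C)`.
#' @param hidden Two hidden widths.
#' @param bottleneck Bottleneck width (the extracted feature vector).
#' @param leaky_slope LeakyReLU slope.
#' @param seed Init seed.
#' @return An `semg_fcae`.
#' @export
build_fcae <- function(input_shape, hidden = c(512L, 128L), bottleneck = 64L,
                       leaky_slope = 0.01, seed = 1L) {
  stopifnot(length(input_shape) == 2L, length(hidden) == 2L)
  n_in <- as.integer(prod(input_shape))
  a <- leaky_slope
  enc <- list(
    nn_layer("flat", "flatten"),
    nn_layer("fe1", "dense", n_in = n_in, n_out = hidden[1L]),
    nn_layer("fe1a", "lrelu", alpha = a),
    nn_layer("fe2", "dense", n_in = hidden[1L], n_out = hidden[2L]),
    nn_layer("fe2a", "lrelu", alpha = a),
    nn_layer("fbott", "dense", n_in = hidden[2L], n_out = bottleneck),
    nn_layer("fbotta", "lrelu", alpha = a)
  )
  dec <- list(
    nn_layer("fd1", "dense", n_in = bottleneck, n_out = hidden[2L]),
    nn_layer("fd1a", "lrelu", alpha = a),
    nn_layer("fd2", "dense", n_in = hidden[2L], n_out = hidden[1L]),
    nn_layer("fd2a", "lrelu", alpha = a),
    nn_layer("frecon", "dense", n_in = hidden[1L], n_out = n_in)
  )
  params <- c(nn_init(enc, substream_seed(seed, "fcae-enc")),
              nn_init(dec, substream_seed(seed, "fcae-dec")))
  structure(
    list(enc_layers = enc, dec_layers = dec, params = params,
         input_shape = as.integer(input_shape), bottleneck = as.integer(bottleneck),
         history = NULL),
    class = "semg_fcae"
  )
}

#' Train the fully-connected autoencoder (MSE, no sparsity)
#' @param model An `semg_fcae`.
#' @param train,val Standardized `semg_segments` or arrays.
#' @param tc A [train_config()].
#' @return The trained `semg_fcae`.
#' @export
train_fcae <- function(model, train, val, tc = train_config()) {
  stopifnot(inherits(model, "semg_fcae"))
  x_tr <- as_segment_array(train); x_va <- as_segment_array(val)
  step_fn <- function(params, idx) {
    xb <- x_tr[idx, , , drop = FALSE]
    fe <- nn_forward(model$enc_layers, params, xb)
    fd <- nn_forward(model$dec_layers, params, fe$out)
    xflat <- xb; dim(xflat) <- dim(fd$out)
    loss <- mean((xflat - fd$out)^2)
    dout <- 2 * (fd$out - xflat) / length(xflat)
    bd <- nn_backward(model$dec_layers, params, fd$caches, dout)
    be <- nn_backward(model$enc_layers, params, fe$caches, bd$dx)
    list(loss = loss, grads = c(be$grads, bd$grads))
  }
  val_fn <- function(params) {
    z <- nn_forward(model$enc_layers, params, x_va, keep_cache = FALSE)$out
    xh <- nn_forward(model$dec_layers, params, z, keep_cache = FALSE)$out
    xflat <- x_va; dim(xflat) <- dim(xh)
    mean((xflat - xh)^2)
  }
  fit <- fit_network(model$params, dim(x_tr)[1L], step_fn, val_fn, tc)
  model$params <- fit$params
  model$history <- fit$history
  model
}

#' Bottleneck features of the fully-connected autoencoder
#' @param model A trained `semg_fcae`.
#' @param batch `semg_segments` or array.
#' @return N x bottleneck feature matrix.
#' @export
encode_fcae <- function(model, batch) {
  x <- as_segment_array(batch)
  nn_forward(model$enc_layers, model$params, x, keep_cache = FALSE)$out
}

#' Reconstruct segments with the fully-connected autoencoder
#' @param model A trained `semg_fcae`.
#' @param batch `semg_segments` or array.
#' @return N x T x C reconstruction (reshaped from the flat output).
#' @export
reconstruct_fcae <- function(model, batch) {
  x <- as_segment_array(batch)
  z <- encode_fcae(model, batch)
  xh <- nn_forward(model$dec_layers, model$params, z, keep_cache = FALSE)$out
  dim(xh) <- dim(x)
  xh
}

# Supervised CNN-LSTM baseline -------------------------------------------------

#' CNN-LSTM configuration
#'
#' @param conv_filters,conv_kernels,conv_strides Two conv front-end blocks.
#' @param hidden LSTM hidden width.
#' @param n_classes Output classes.
#' @param leaky_slope LeakyReLU slope for the conv blocks.
#' @param seed Init seed.
#' @return A `cnn_lstm_config`.
#' @export
cnn_lstm_config <- function(conv_filters = c(16L, 16L), conv_kernels = c(7L, 5L),
                            conv_strides = c(5L, 2L), hidden = 24L,
                            n_classes = 6L, leaky_slope = 0.01, seed = 1L) {
  structure(
    list(conv_filters = as.integer(conv_filters), conv_kernels = as.integer(conv_kernels),
         conv_strides = as.integer(conv_strides), hidden = as.integer(hidden),
         n_classes = as.integer(n_classes), leaky_slope = leaky_slope,
         seed = as.integer(seed)),
    class = "cnn_lstm_config"
  )
}

#' Build the end-to-end supervised CNN-LSTM baseline
#'
#' Conv front-end (two strided blocks with LeakyReLU), a single LSTM whose
#' final hidden state feeds a dense softmax output. When `reference_params`
#' is supplied, the total trainable parameter count is checked against it
#' and a warning with both counts is emitted if they differ by more than
#' `capacity_tol` (capacity-matched comparison).
#'
#' @param config A `cnn_lstm_config`.
#' @param input_shape `c(T, C)`.
#' @param class_list Ordered class list (length `n_classes`).
#' @param reference_params Optional reference parameter count to match.
#' @param capacity_tol Relative tolerance of the capacity match.
#' @return An `semg_cnn_lstm`.
#' @export
build_cnn_lstm <- function(config, input_shape, class_list,
                           reference_params = NULL, capacity_tol = 0.2) {
  stopifnot(inherits(config, "cnn_lstm_config"), length(input_shape) == 2L)
  class_list <- as.character(class_list)
  stopifnot(length(class_list) == config$n_classes)
  a <- config$leaky_slope
  f <- config$conv_filters; k <- config$conv_kernels; s <- config$conv_strides
  layers <- list(
    nn_layer("cl1", "conv", k = k[1L], stride = s[1L], in_ch = input_shape[2L],
             out_ch = f[1L]),
    nn_layer("cl1a", "lrelu", alpha = a),
    nn_layer("cl2", "conv", k = k[2L], stride = s[2L], in_ch = f[1L], out_ch = f[2L]),
    nn_layer("cl2a", "lrelu", alpha = a),
    nn_layer("rnn", "lstm", n_in = f[2L], hidden = config$hidden),
    nn_layer("clout", "dense", n_in = config$hidden, n_out = config$n_classes)
  )
  params <- nn_init(layers, substream_seed(config$seed, "cnn-lstm"))
  n_par <- sum(vapply(layers, layer_param_count, numeric(1)))
  if (!is.null(reference_params)) {
    rel <- abs(n_par - reference_params) / reference_params
    if (rel > capacity_tol) {
      warning(sprintf(
        "capacity mismatch: CNN-LSTM has %d parameters vs reference %d (%.0f%% off)",
        n_par, as.integer(reference_params), 100 * rel))
    }
  }
  structure(
    list(layers = layers, params = params, config = config,
         class_list = class_list, input_shape = as.integer(input_shape),
         n_params = n_par, history = NULL),
    class = "semg_cnn_lstm"
  )
}

#' Train the CNN-LSTM baseline end-to-end (supervised)
#' @param model An `semg_cnn_lstm`.
#' @param train,val Standardized `semg_segments`.
#' @param tc A [train_config()].
#' @return The trained model.
#' @export
train_cnn_lstm <- function(model, train, val, tc = train_config()) {
  stopifnot(inherits(model, "semg_cnn_lstm"))
  check_labels(train$labels, model$class_list)
  x_tr <- as_segment_array(train); x_va <- as_segment_array(val)
  y_tr <- one_hot(train$labels, model$class_list)
  y_va <- one_hot(val$labels, model$class_list)
  step_fn <- function(params, idx) {
    fw <- nn_forward(model$layers, params, x_tr[idx, , , drop = FALSE])
    p <- softmax_rows(fw$out)
    yb <- y_tr[idx, , drop = FALSE]
    bw <- nn_backward(model$layers, params, fw$caches, (p - yb) / nrow(yb))
    list(loss = cross_entropy(p, yb), grads = bw$grads)
  }
  val_fn <- function(params) {
    fw <- nn_forward(model$layers, params, x_va, keep_cache = FALSE)
    cross_entropy(softmax_rows(fw$out), y_va)
  }
  fit <- fit_network(model$params, dim(x_tr)[1L], step_fn, val_fn, tc)
  model$params <- fit$params
  model$history <- fit$history
  model
}

#' @export
predict.semg_cnn_lstm <- function(object, batch, ...) {
  x <- as_segment_array(batch)
  prob <- softmax_rows(nn_forward(object$layers, object$params, x, keep_cache = FALSE)$out)
  colnames(prob) <- object$class_list
  list(prob = prob,
       labels = object$class_list[max.col(prob, ties.method = "first")])
}

# Cost accounting --------------------------------------------------------------

# analytic per-layer cost, tracking the temporal shape; multiply-accumulate
# counted as 2 FLOPs throughout
layer_cost <- function(ly, shape) {
  if (ly$type == "conv") {
    t_out <- shape[1L] %/% ly$stride
    list(shape = c(t_out, ly$out_ch),
         flops = 2 * ly$k * ly$in_ch * ly$out_ch * t_out)
  } else if (ly$type == "tconv") {
    t_out <- shape[1L] * ly$stride
    list(shape = c(t_out, ly$out_ch),
         flops = 2 * ly$k * ly$in_ch * ly$out_ch * shape[1L])
  } else if (ly$type == "lrelu") {
    list(shape = shape, flops = prod(shape))
  } else if (ly$type == "featnorm") {
    list(shape = shape, flops = 4 * prod(shape))
  } else if (ly$type == "attnpool") {
    t_in <- shape[1L]
    list(shape = ly$dim,
         flops = 2 * t_in * ly$dim * ly$attn_dim + 2 * t_in * ly$attn_dim +
           5 * t_in + 2 * t_in * ly$dim)
  } else if (ly$type == "dense") {
    list(shape = ly$n_out, flops = 2 * ly$n_in * ly$n_out)
  } else if (ly$type == "lstm") {
    list(shape = ly$hidden,
         flops = shape[1L] * (2 * 4 * ly$hidden * (ly$n_in + ly$hidden) + 10 * ly$hidden))
  } else if (ly$type == "flatten") {
    list(shape = prod(shape), flops = 0)
  } else stop("unknown layer type")
}

cost_of_layers <- function(layers, shape, bytes_per_param = 4) {
  n_par <- sum(vapply(layers, layer_param_count, numeric(1)))
  flops <- 0
  peak <- prod(shape)
  for (ly in layers) {
    r <- layer_cost(ly, shape)
    flops <- flops + r$flops
    peak <- max(peak, prod(shape) + prod(r$shape))
    shape <- r$shape
  }
  list(parameter_count = n_par,
       static_bytes = n_par * bytes_per_param,
       runtime_bytes_estimate = peak * bytes_per_param,
       flops_per_inference = flops)
}

#' Analytic model cost report
#'
#' Parameter count, static storage, a peak-activation runtime-memory
#' estimate, and FLOPs per single-segment inference, derived purely from
#' layer shapes (one multiply-accumulate = 2 FLOPs; `bytes_per_param`
#' defaults to 4, the float32 deployment convention). The report depends
#' only on the architecture, never on parameter values. For the classifier
#' the inference path (frozen encoder + head) is costed; for autoencoders
#' the full encoder + decoder.
#'
#' @param model An `semg_csae`, `semg_classifier`, `semg_fcae`, or
#'   `semg_cnn_lstm`.
#' @param bytes_per_param Bytes per parameter for the memory figures.
#' @return List: `parameter_count`, `static_bytes`,
#'   `runtime_bytes_estimate`, `flops_per_inference`.
#' @export
model_cost_report <- function(model, bytes_per_param = 4) {
  shape_in <- c(model$input_shape[1L], model$input_shape[2L])
  layers <- if (inherits(model, "semg_csae")) {
    c(model$enc_layers, model$dec_layers)
  } else if (inherits(model, "semg_classifier")) {
    c(model$enc_layers, model$head_layers)
  } else if (inherits(model, "semg_fcae")) {
    c(model$enc_layers, model$dec_layers)
  } else if (inherits(model, "semg_cnn_lstm")) {
    model$layers
  } else stop("unsupported model class", call. = FALSE)
  cost_of_layers(layers, shape_in, bytes_per_param)
}

# Shared-harness benchmark ------------------------------------------------------

#' Benchmark competing pipelines under identical folds and scalers
#'
#' Runs the requested methods on the same leave-one-subject-out folds, with
#' the identical fold-wise scaler, and reports cross-fold mean and SE of
#' micro-F1 plus analytic cost figures. Methods: `csae` (sparse autoencoder
#' features + attention head), `cae0` (identical architecture, lambda = 0),
#' `fcae` (flattened dense autoencoder bottleneck + random forest),
#' `classical_rf` (time-domain features + random forest), `cnn_lstm`
#' (end-to-end supervised).
#'
#' @param cohort List of `semg_recording`s.
#' @param methods Character subset of the five method names.
#' @param csae_cfg,clf_cfg,tc_csae,tc_clf Main-pipeline configurations.
#' @param fcae_hidden,fcae_bottleneck FCAE architecture.
#' @param cnn_cfg A `cnn_lstm_config` (n_classes is overridden per cohort).
#' @param rf_ntree Trees for the random-forest stages.
#' @param window_ms,stride_ms,folds,seed As in [run_loso()].
#' @return data.frame: method, mean_f1, se_f1, parameter_count, static_mb,
#'   runtime_mb, gflops (NA where no neural model is involved), plus a
#'   `per_fold` attribute with the fold-level scores.
#' @export
benchmark_methods <- function(cohort,
                              methods = c("csae", "cae0", "fcae", "classical_rf", "cnn_lstm"),
                              csae_cfg = csae_config(), clf_cfg = classifier_config(),
                              tc_csae = train_config(), tc_clf = train_config(),
                              fcae_hidden = c(512L, 128L), fcae_bottleneck = 64L,
                              cnn_cfg = cnn_lstm_config(), rf_ntree = 500L,
                              window_ms = 250, stride_ms = 125,
                              folds = NULL, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  plans <- make_loso_folds(cohort)
  if (is.null(folds)) folds <- seq_along(plans)
  scores <- matrix(NA_real_, nrow = length(folds), ncol = length(methods),
                   dimnames = list(NULL, methods))
  costs <- list()
  for (j in seq_along(folds)) {
    plan <- plans[[folds[j]]]
    fold_seed <- substream_seed(seed, paste0("bench-fold:", folds[j]))
    segs <- fold_segments(cohort, plan, window_ms, stride_ms)
    scaler <- fit_scaler(segs$source_train)
    segs <- lapply(segs, apply_scaler, stats = scaler)
    class_list <- sort(unique(segs$source_train$labels))
    t_len <- dim(segs$source_train$segments)[2L]
    c_ch <- dim(segs$source_train$segments)[3L]
    y_test <- segs$source_test$labels

    for (m in methods) {
      if (m %in% c("csae", "cae0")) {
        cfg <- csae_cfg
        if (m == "cae0") cfg$l1_coeff <- 0
        cfg$seed <- substream_seed(fold_seed, paste0(m, "-ae"))
        ae <- build_csae(cfg, c(t_len, c_ch))
        tc_a <- tc_csae; tc_a$seed <- substream_seed(fold_seed, paste0(m, "-ae-tr"))
        ae <- train_csae(ae, segs$source_train, segs$source_val, tc_a)
        ccfg <- clf_cfg; ccfg$n_classes <- length(class_list)
        ccfg$seed <- substream_seed(fold_seed, paste0(m, "-clf"))
        clf <- build_classifier(ae, ccfg, class_list)
        tc_c <- tc_clf; tc_c$seed <- substream_seed(fold_seed, paste0(m, "-clf-tr"))
        clf <- train_classifier(clf, segs$source_train, segs$source_val, tc_c)
        pred <- predict(clf, segs$source_test)$labels
        if (j == 1L) costs[[m]] <- model_cost_report(clf)
      } else if (m == "fcae") {
        fc <- build_fcae(c(t_len, c_ch), fcae_hidden, fcae_bottleneck,
                         seed = substream_seed(fold_seed, "fcae"))
        tc_a <- tc_csae; tc_a$seed <- substream_seed(fold_seed, "fcae-tr")
        fc <- train_fcae(fc, segs$source_train, segs$source_val, tc_a)
        rf <- train_rf_baseline(encode_fcae(fc, segs$source_train),
                                segs$source_train$labels, ntree = rf_ntree,
                                seed = substream_seed(fold_seed, "fcae-rf"))
        pred <- predict(rf, encode_fcae(fc, segs$source_test))
        if (j == 1L) costs[[m]] <- model_cost_report(fc)
      } else if (m == "classical_rf") {
        rf <- train_rf_baseline(classical_features(segs$source_train),
                                segs$source_train$labels, ntree = rf_ntree,
                                seed = substream_seed(fold_seed, "cls-rf"))
        pred <- predict(rf, classical_features(segs$source_test))
        if (j == 1L) costs[[m]] <- NULL
      } else { # cnn_lstm
        ref <- NULL
        if ("csae" %in% names(costs)) ref <- costs$csae$parameter_count
        ccfg <- cnn_cfg; ccfg$n_classes <- length(class_list)
        ccfg$seed <- substream_seed(fold_seed, "cnn")
        cl <- build_cnn_lstm(ccfg, c(t_len, c_ch), class_list, reference_params = ref)
        tc_c <- tc_clf; tc_c$seed <- substream_seed(fold_seed, "cnn-tr")
        cl <- train_cnn_lstm(cl, segs$source_train, segs$source_val, tc_c)
        pred <- predict(cl, segs$source_test)$labels
        if (j == 1L) costs[[m]] <- model_cost_report(cl)
      }
      scores[j, m] <- unname(prf1(y_test, pred, class_list)$micro["f1"])
    }
  }
  rows <- lapply(methods, function(m) {
    ms <- mean_se(scores[, m])
    co <- costs[[m]]
    data.frame(
      method = m, mean_f1 = unname(ms["mean"]), se_f1 = unname(ms["se"]),
      parameter_count = if (is.null(co)) NA_real_ else co$parameter_count,
      static_mb = if (is.null(co)) NA_real_ else co$static_bytes / 2^20,
      runtime_mb = if (is.null(co)) NA_real_ else co$runtime_bytes_estimate / 2^20,
      gflops = if (is.null(co)) NA_real_ else co$flops_per_inference / 1e9,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "per_fold") <- scores
  out
}
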