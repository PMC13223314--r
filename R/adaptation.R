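# Transfer protocols: few-shot user calibration and incremental class
# expansion with softmax weight transfer ---------------------------------------

#' Few-shot calibration to a new user
#'
#' Fine-tunes only the highest-level decision-making layers — both MLP
#' stages and the softmax output layer — on a minimal calibration set from
#' the unseen target subject. The encoder, layer normalization, temporal
#' convolution, and attention parameters are frozen and come out
#' bit-identical. Uses the same optimizer / early-stopping machinery as
#' initial training.
#'
#' @param model A trained `semg_classifier`.
#' @param calib,val Standardized `semg_segments` from the target subject only
#'   (calibration trial and validation trial of the split plan).
#' @param tc A [train_config()]; `max_epochs = 0` returns the model
#'   unchanged.
#' @return The adapted `semg_classifier`.
#' @export
few_shot_finetune <- function(model, calib, val, tc = train_config()) {
  stopifnot(inherits(model, "semg_classifier"))
  check_labels(calib$labels, model$class_list)
  check_labels(val$labels, model$class_list)
  groups <- classifier_param_groups(model)
  trainable <- c(groups$mlp_fc, groups$output_softmax)
  z_ca <- encode_with(model, calib)
  z_va <- encode_with(model, val)
  y_ca <- one_hot(calib$labels, model$class_list)
  y_va <- one_hot(val$labels, model$class_list)
  train_head(model, z_ca, y_ca, z_va, y_va, tc, trainable = trainable)
}

#' Expand the output layer to new classes with weight transfer
#'
#' Removes the K-unit softmax output layer and appends a freshly initialized
#' layer with one unit per entry of `new_class_list`. The learned weights
#' and biases of every original class are copied into its corresponding new
#' unit, so (with the shared frozen features) the original classes'
#' pre-softmax logits are preserved exactly; the remaining units keep their
#' random initialization. All other parameters are carried over unchanged.
#'
#' @param model A trained `semg_classifier` (e.g. 6 classes).
#' @param new_class_list Ordered ids of the expanded set; must contain every
#'   original class.
#' @param seed Seed for the new units' initialization.
#' @return An `semg_classifier` over `new_class_list` (untrained head output).
#' @export
expand_classes <- function(model, new_class_list, seed = 1L) {
  stopifnot(inherits(model, "semg_classifier"))
  new_class_list <- as.character(new_class_list)
  missing_old <- setdiff(model$class_list, new_class_list)
  if (length(missing_old) > 0L) {
    stop(sprintf("original class(es) missing from the new class list: %s",
                 paste(missing_old, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(new_class_list)) stop("`new_class_list` has duplicates", call. = FALSE)
  k_new <- length(new_class_list)
  cfg <- model$config
  cfg$n_classes <- as.integer(k_new)
  out <- model
  out$config <- cfg
  out$class_list <- new_class_list
  # rebuild only the output layer
  out$head_layers[[length(out$head_layers)]] <-
    nn_layer("out", "dense", n_in = cfg$mlp_dims[2L], n_out = k_new)
  fresh <- with_seed(substream_seed(seed, "expand"), {
    list(
      W = he_normal(c(cfg$mlp_dims[2L], k_new), cfg$mlp_dims[2L]),
      b = numeric(k_new)
    )
  })
  old_idx <- match(model$class_list, new_class_list)
  fresh$W[, old_idx] <- model$head_params$out_W
  fresh$b[old_idx] <- model$head_params$out_b
  out$head_params$out_W <- fresh$W
  out$head_params$out_b <- fresh$b
  out$history <- NULL
  out
}

#' Two-phase training of an expanded classifier
#'
#' Phase I freezes everything except the new softmax output layer and trains
#' it on the expanded class set, rapidly mapping the fixed features to all
#' classes. The best Phase-I checkpoint is kept; Phase II then unfreezes the
#' whole classifier head (layer norm, convolution, attention, MLP, output) —
#' the encoder stays frozen — and continues at a significantly lower
#' learning rate to refine the class boundaries.
#'
#' @param model An expanded `semg_classifier` from [expand_classes()].
#' @param train,val Standardized `semg_segments` over the expanded class set,
#'   partitioned like the initial training data.
#' @param tc1,tc2 [train_config()]s for the two phases; a
#'   `tc2$learning_rate >= tc1$learning_rate` triggers a protocol-deviation
#'   warning but proceeds.
#' @return List with `model` (after Phase II), `phase1_model`, and
#'   `history` (both phases).
#' @export
two_phase_train <- function(model, train, val, tc1 = train_config(),
                            tc2 = train_config(learning_rate = tc1$learning_rate * 0.1)) {
  stopifnot(inherits(model, "semg_classifier"))
  if (tc2$learning_rate >= tc1$learning_rate) {
    warning("Phase II learning rate is not lower than Phase I (protocol deviation)")
  }
  check_labels(train$labels, model$class_list)
  groups <- classifier_param_groups(model)
  z_tr <- encode_with(model, train)
  z_va <- encode_with(model, val)
  y_tr <- one_hot(train$labels, model$class_list)
  y_va <- one_hot(val$labels, model$class_list)
  m1 <- train_head(model, z_tr, y_tr, z_va, y_va, tc1,
                   trainable = groups$output_softmax)
  h1 <- m1$history
  m2 <- train_head(m1, z_tr, y_tr, z_va, y_va, tc2,
                   trainable = unlist(groups, use.names = FALSE))
  h2 <- m2$history
  m2$history <- list(phase1 = h1, phase2 = h2)
  list(model = m2, phase1_model = m1, history = m2$history)
}

#' Per-class forgetting report after class expansion
#'
#' Compares per-class F1 on the original classes before and after expansion.
#' The expanded model is scored two ways: with its full expanded-set argmax
#' (new classes can steal instances) and restricted to the original classes'
#' output units.
#'
#' @param model6 The original classifier.
#' @param model10 The expanded classifier.
#' @param test6 Standardized `semg_segments` containing only original classes.
#' @return A data.frame with per-class F1 before, after (full and
#'   restricted argmax), and the corresponding deltas.
#' @export
forgetting_report <- function(model6, model10, test6) {
  stopifnot(inherits(model6, "semg_classifier"), inherits(model10, "semg_classifier"))
  check_labels(test6$labels, model6$class_list)
  base <- model6$class_list
  pred6 <- predict(model6, test6)$labels
  p10 <- predict(model10, test6)
  pred10_full <- p10$labels
  keep <- match(base, model10$class_list)
  prob_restr <- p10$prob[, keep, drop = FALSE]
  pred10_restr <- base[max.col(prob_restr, ties.method = "first")]
  f1_of <- function(pred, classes) {
    m <- prf1(test6$labels, pred, classes)
    m$per_class$f1[match(base, m$per_class$class)]
  }
  before <- f1_of(pred6, base)
  after_full <- f1_of(pred10_full, union(base, unique(pred10_full)))
  after_restr <- f1_of(pred10_restr, base)
  data.frame(
    class = base,
    f1_before = before,
    f1_after_full = after_full,
    f1_after_restricted = after_restr,
    delta_full = after_full - before,
    delta_restricted = after_restr - before,
    stringsAsFactors = FALSE
  )
}
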