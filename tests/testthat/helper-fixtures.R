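# Shared fixtures: everything is generated in code at test time.

# tiny deterministic recording: L samples, C channels
tiny_recording <- function(L = 1000L, C = 2L, fs = 4000, subject = "S1",
                           gesture = "G01", trial = 1L, seed = 1L) {
  samples <- with_seed2(seed, matrix(stats::rnorm(L * C), L, C))
  new_recording(subject, gesture, trial, samples, fs)
}

with_seed2 <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# very small multi-subject cohort for structural tests (fast to generate)
tiny_cohort_config <- function(seed = 1L, n_subjects = 2L, n_gestures = 3L,
                               n_trials = 6L) {
  synth_config(
    n_subjects = n_subjects, n_gestures = n_gestures, n_trials = n_trials,
    fs = 500, trial_duration_s = 1, carrier_band = c(20, 120),
    subject_shift_scale = 0.1, noise_floor = 0.05, seed = seed
  )
}

# toy autoencoder config matching a 100-sample window at fs 500 (T = 100)
toy_csae_config <- function(seed = 1L, lambda = 1e-7) {
  csae_config(enc_filters = c(6L, 8L), enc_kernels = c(7L, 5L, 3L),
              enc_strides = c(5L, 2L), latent_filters = 4L,
              l1_coeff = lambda, seed = seed)
}

toy_clf_config <- function(n_classes = 3L, seed = 1L) {
  classifier_config(head_conv_filters = 8L, head_conv_kernel = 3L,
                    attention_dim = 6L, mlp_dims = c(12L, 8L),
                    n_classes = n_classes, seed = seed)
}

fast_tc <- function(epochs = 3L, seed = 1L) {
  train_config(batch_size = 64L, max_epochs = epochs, learning_rate = 2e-3,
               early_stop_patience = 50L, plateau_patience = 25L, seed = seed)
}

# standardized fold segments of the tiny cohort, cached per session
.fixture_cache <- new.env(parent = emptyenv())

tiny_fold <- function(seed = 1L) {
  key <- paste0("fold", seed)
  if (is.null(.fixture_cache[[key]])) {
    cohort <- generate_cohort(tiny_cohort_config(seed))
    plans <- make_loso_folds(cohort)
    segs <- fold_segments(cohort, plans[[1L]], window_ms = 200, stride_ms = 100)
    scaler <- fit_scaler(segs$source_train)
    .fixture_cache[[key]] <- list(
      cohort = cohort, plan = plans[[1L]],
      segs = lapply(segs, apply_scaler, stats = scaler), scaler = scaler
    )
  }
  .fixture_cache[[key]]
}

# a small trained autoencoder + classifier over the tiny cohort, shared by
# classifier/adaptation tests
tiny_trained_models <- function() {
  if (is.null(.fixture_cache$models)) {
    fx <- tiny_fold(1L)
    ae <- build_csae(toy_csae_config(7L), c(100L, 2L))
    ae <- train_csae(ae, fx$segs$source_train, fx$segs$source_val, fast_tc(4L, 11L))
    cls <- sort(unique(fx$segs$source_train$labels))
    clf <- build_classifier(ae, toy_clf_config(length(cls), 13L), cls)
    clf <- train_classifier(clf, fx$segs$source_train, fx$segs$source_val,
                            fast_tc(5L, 17L))
    .fixture_cache$models <- list(fx = fx, ae = ae, clf = clf, cls = cls)
  }
  .fixture_cache$models
}

# central finite-difference gradient of f at p
num_grad <- function(f, p, eps = 1e-5) {
  g <- numeric(length(p))
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}
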