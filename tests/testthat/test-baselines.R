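test_that("classical time-domain features match direct counts on anchor signals", {
  const <- matrix(3, 100, 1)
  f <- classical_features(const)
  expect_equal(unname(f["ch1_mav"]), 3)
  expect_equal(unname(f["ch1_var"]), 0)
  expect_equal(unname(f["ch1_zc"]), 0)
  expect_equal(unname(f["ch1_wl"]), 0)
  expect_equal(unname(f["ch1_rms"]), 3)

  alt <- matrix(rep(c(1, -1), 500), ncol = 1)
  fa <- classical_features(alt)
  expect_equal(unname(fa["ch1_zc"]), 999)
  expect_equal(unname(fa["ch1_wl"]), 1998)

  # brute-force loop oracle on random segments
  set.seed(12)
  x <- matrix(rnorm(200), 100, 2)
  got <- classical_features(x)
  for (ci in 1:2) {
    v <- x[, ci]
    zc <- 0; wl <- 0; ssc <- 0
    for (t in 2:length(v)) {
      if (v[t] * v[t - 1] < 0) zc <- zc + 1
      wl <- wl + abs(v[t] - v[t - 1])
    }
    for (t in 3:length(v)) {
      if ((v[t] - v[t - 1]) * (v[t - 1] - v[t - 2]) < 0) ssc <- ssc + 1
    }
    pre <- paste0("ch", ci, "_")
    expect_equal(unname(got[paste0(pre, "mav")]), mean(abs(v)))
    expect_equal(unname(got[paste0(pre, "var")]), var(v))
    expect_equal(unname(got[paste0(pre, "zc")]), zc)
    expect_equal(unname(got[paste0(pre, "wl")]), wl, tolerance = 1e-12)
    expect_equal(unname(got[paste0(pre, "ssc")]), ssc)
    expect_equal(unname(got[paste0(pre, "rms")]), sqrt(mean(v^2)))
  }
})

test_that("random-forest baseline is seed-reproducible and beats chance on separable data", {
  fx <- tiny_fold(1L)
  ftr <- classical_features(fx$segs$source_train)
  fte <- classical_features(fx$segs$source_test)
  rf1 <- train_rf_baseline(ftr, fx$segs$source_train$labels, ntree = 100L, seed = 9L)
  rf2 <- train_rf_baseline(ftr, fx$segs$source_train$labels, ntree = 100L, seed = 9L)
  expect_identical(predict(rf1, fte), predict(rf2, fte))
  acc <- mean(predict(rf1, fte) == fx$segs$source_test$labels)
  expect_gt(acc, 2 / 3) # far above the 1/3 chance level
})

test_that("the dense autoencoder flattens, reconstructs the input shape, and trains", {
  fx <- tiny_fold(1L)
  fc <- build_fcae(c(100L, 2L), hidden = c(32L, 16L), bottleneck = 8L, seed = 3L)
  fc <- train_fcae(fc, fx$segs$source_train, fx$segs$source_val, fast_tc(2L))
  xh <- reconstruct_fcae(fc, fx$segs$source_val)
  expect_equal(dim(xh), dim(fx$segs$source_val$segments))
  z <- encode_fcae(fc, fx$segs$source_val)
  expect_equal(ncol(z), 8L)
  # dense layers are equivariant to a fixed input permutation: permuting
  # time points identically everywhere permutes first-layer weights only,
  # so the achievable reconstruction loss is unchanged by construction;
  # check the forward pass identity that underlies it
  perm <- with_seed2(31L, sample(100L))
  xp <- fx$segs$source_val$segments[, perm, , drop = FALSE]
  fcp <- fc
  # apply the same permutation to the first dense layer's rows (time-major
  # flattening: rows are (t, c) pairs with t fastest)
  rows <- as.vector(outer(perm, (0:1) * 100L, "+"))
  fcp$params$fe1_W <- fc$params$fe1_W[rows, ]
  expect_equal(encode_fcae(fcp, xp), encode_fcae(fc, fx$segs$source_val),
               tolerance = 1e-12)
})

test_that("the CNN-LSTM baseline trains above chance and checks capacity", {
  fx <- tiny_fold(1L)
  cls <- sort(unique(fx$segs$source_train$labels))
  cfg <- cnn_lstm_config(conv_filters = c(6L, 6L), conv_kernels = c(7L, 5L),
                         conv_strides = c(5L, 2L), hidden = 8L,
                         n_classes = 3L, seed = 4L)
  cn <- build_cnn_lstm(cfg, c(100L, 2L), cls)
  expect_gt(cn$n_params, 0)
  expect_warning(
    build_cnn_lstm(cfg, c(100L, 2L), cls, reference_params = cn$n_params * 10),
    "capacity mismatch"
  )
  cn <- train_cnn_lstm(cn, fx$segs$source_train, fx$segs$source_val, fast_tc(40L, 5L))
  pred <- predict(cn, fx$segs$source_test)
  expect_lt(max(abs(rowSums(pred$prob) - 1)), 1e-6)
  acc <- mean(pred$labels == fx$segs$source_test$labels)
  expect_gt(acc, 0.45) # chance is 1/3
  # deterministic under a fixed seed
  cn2 <- build_cnn_lstm(cfg, c(100L, 2L), cls)
  cn2 <- train_cnn_lstm(cn2, fx$segs$source_train, fx$segs$source_val, fast_tc(40L, 5L))
  expect_identical(predict(cn2, fx$segs$source_test)$labels, pred$labels)
})

test_that("model cost reports are analytic, architecture-deterministic, and match hand counts", {
  # single dense layer 10 -> 5 with bias: 55 parameters
  expect_equal(csaemg:::layer_param_count(csaemg:::nn_layer("d", "dense", n_in = 10L, n_out = 5L)),
               55)
  # 1-D conv, 2 -> 4 filters, kernel 3, stride 1, length 10, same padding:
  # 10 output positions x (3*2*4) MACs x 2 FLOPs/MAC
  conv_cost <- csaemg:::layer_cost(
    csaemg:::nn_layer("c", "conv", k = 3L, stride = 1L, in_ch = 2L, out_ch = 4L),
    c(10L, 2L))
  expect_equal(conv_cost$flops, 2 * 3 * 2 * 4 * 10)
  expect_equal(conv_cost$shape, c(10L, 4L))

  m <- tiny_trained_models()
  r1 <- model_cost_report(m$clf)
  r2 <- model_cost_report(m$clf)
  expect_identical(r1, r2)
  expect_equal(r1$static_bytes, r1$parameter_count * 4)
  # invariant to parameter values
  clf2 <- m$clf
  clf2$head_params <- lapply(clf2$head_params, function(p) p * 2)
  expect_identical(model_cost_report(clf2), r1)
  # parameter count agrees with the actual parameter storage
  stored <- sum(vapply(c(m$clf$enc_params, m$clf$head_params), length, integer(1)))
  expect_equal(r1$parameter_count, stored)
})

test_that("benchmark harness shares folds/scaler and emits a cost table", {
  cohort <- generate_cohort(tiny_cohort_config(23L))
  tab <- benchmark_methods(cohort, c("classical_rf", "csae"),
                           csae_cfg = toy_csae_config(), clf_cfg = toy_clf_config(3L),
                           tc_csae = fast_tc(2L), tc_clf = fast_tc(2L),
                           rf_ntree = 60L, window_ms = 200, stride_ms = 100,
                           folds = 1L, seed = 8L)
  expect_equal(tab$method, c("classical_rf", "csae"))
  expect_true(all(is.finite(tab$mean_f1)))
  expect_true(is.na(tab$static_mb[1L])) # no neural model for classical features
  expect_gt(tab$static_mb[2L], 0)
  expect_equal(dim(attr(tab, "per_fold")), c(1L, 2L))
})
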