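# The convolution/attention/normalization engine is hand-written, so its
# gradients are validated against central finite differences on toy models.

test_that("composite autoencoder loss gradients match finite differences", {
  ae <- build_csae(csae_config(enc_filters = c(3L, 4L), enc_kernels = c(5L, 4L, 3L),
                               enc_strides = c(2L, 3L), latent_filters = 2L,
                               l1_coeff = 0.05, seed = 5L),
                   c(12L, 2L))
  x <- with_seed2(8L, array(rnorm(3 * 12 * 2), c(3, 12, 2)))
  got <- csaemg:::csae_batch_grad(ae, x)
  loss_at <- function(params) {
    m <- ae; m$params <- params
    z <- encode(m, x)
    csae_loss(x, decode(m, z), z, 0.05)
  }
  expect_equal(got$loss, loss_at(ae$params), tolerance = 1e-12)
  for (nm in names(ae$params)) {
    f <- function(v) { p <- ae$params; p[[nm]][] <- v; loss_at(p) }
    ng <- num_grad(f, as.numeric(ae$params[[nm]]))
    expect_lt(max_rel_err(as.numeric(got$grads[[nm]]), ng), 1e-4)
  }
})

test_that("classifier head gradients (normalization, conv, attention, MLP) match finite differences", {
  layers <- csaemg:::head_layer_graph(3L, toy_clf_config(3L, 2L), 3L)
  params <- csaemg:::nn_init(layers, 21L)
  params$ln_mu <- c(0.2, -0.1, 0.05) # non-trivial frozen buffers
  params$ln_sigma <- c(1.3, 0.8, 1.1)
  buffers <- c("ln_mu", "ln_sigma")
  z <- with_seed2(22L, array(rnorm(4 * 6 * 3), c(4, 6, 3)))
  y <- one_hot(c("a", "b", "c", "a"), c("a", "b", "c"))
  loss_at <- function(params) {
    out <- csaemg:::nn_forward(layers, params, z, keep_cache = FALSE)$out
    cross_entropy(csaemg:::softmax_rows(out), y)
  }
  fw <- csaemg:::nn_forward(layers, params, z)
  p <- csaemg:::softmax_rows(fw$out)
  bw <- csaemg:::nn_backward(layers, params, fw$caches, (p - y) / nrow(y))
  for (nm in setdiff(names(params), buffers)) {
    f <- function(v) { pp <- params; pp[[nm]][] <- v; loss_at(pp) }
    ng <- num_grad(f, as.numeric(params[[nm]]))
    expect_lt(max_rel_err(as.numeric(bw$grads[[nm]]), ng), 1e-4)
  }
})

test_that("LSTM backpropagation matches finite differences", {
  layers <- list(csaemg:::nn_layer("l", "lstm", n_in = 2L, hidden = 3L),
                 csaemg:::nn_layer("o", "dense", n_in = 3L, n_out = 2L))
  params <- csaemg:::nn_init(layers, 31L)
  x <- with_seed2(32L, array(rnorm(3 * 5 * 2), c(3, 5, 2)))
  y <- one_hot(c("a", "b", "a"), c("a", "b"))
  loss_at <- function(params) {
    out <- csaemg:::nn_forward(layers, params, x, keep_cache = FALSE)$out
    cross_entropy(csaemg:::softmax_rows(out), y)
  }
  fw <- csaemg:::nn_forward(layers, params, x)
  p <- csaemg:::softmax_rows(fw$out)
  bw <- csaemg:::nn_backward(layers, params, fw$caches, (p - y) / nrow(y))
  for (nm in names(params)) {
    f <- function(v) { pp <- params; pp[[nm]][] <- v; loss_at(pp) }
    ng <- num_grad(f, as.numeric(params[[nm]]))
    expect_lt(max_rel_err(as.numeric(bw$grads[[nm]]), ng), 1e-4)
  }
})

test_that("encoder/decoder stride symmetry restores the input shape for random legal configs", {
  set.seed(77)
  for (i in 1:12) {
    s1 <- sample(2:5, 1); s2 <- sample(2:4, 1)
    t_in <- s1 * s2 * sample(2:6, 1)
    k1 <- s1 + sample(0:3, 1); k2 <- s2 + sample(0:2, 1)
    cfg <- csae_config(enc_filters = c(3L, 4L), enc_kernels = c(k1, k2, 3L),
                       enc_strides = c(s1, s2), latent_filters = 3L, seed = i)
    c_ch <- sample(1:3, 1)
    ae <- build_csae(cfg, c(t_in, c_ch))
    x <- array(rnorm(2 * t_in * c_ch), c(2, t_in, c_ch))
    z <- encode(ae, x)
    expect_equal(dim(z), c(2L, t_in / (s1 * s2), 3L))
    expect_lt(dim(z)[2L], t_in) # T' < T
    expect_equal(dim(decode(ae, z)), dim(x))
  }
})

test_that("illegal geometries fail at build time", {
  expect_error(build_csae(toy_csae_config(), c(101L, 2L)), "divisible")
  expect_error(csae_config(enc_kernels = c(3L, 5L, 3L), enc_strides = c(4L, 5L)),
               "kernel")
})

test_that("training loop restores best-validation parameters and supports zero epochs", {
  fx <- tiny_fold(1L)
  ae0 <- build_csae(toy_csae_config(3L), c(100L, 2L))
  same <- train_csae(ae0, fx$segs$source_train, fx$segs$source_val, fast_tc(0L))
  expect_identical(same$params, ae0$params)

  tc <- train_config(batch_size = 64L, max_epochs = 6L, learning_rate = 2e-3,
                     early_stop_patience = 2L, plateau_patience = 2L, seed = 4L)
  tr <- train_csae(ae0, fx$segs$source_train, fx$segs$source_val, tc)
  h <- tr$history
  expect_lte(h$best_epoch, h$stopped_epoch)
  expect_equal(length(h$val_loss), h$stopped_epoch)
  # validation loss of the returned parameters equals the recorded best
  x_va <- fx$segs$source_val$segments
  z <- encode(tr, x_va)
  got <- csae_loss(x_va, decode(tr, z), z, tr$config$l1_coeff)
  expect_equal(got, min(h$val_loss), tolerance = 1e-10)
})

test_that("plateau scheduler reduces the learning rate when validation stalls", {
  fx <- tiny_fold(1L)
  ae0 <- build_csae(toy_csae_config(3L), c(100L, 2L))
  tc <- train_config(batch_size = 512L, max_epochs = 10L, learning_rate = 5,
                     early_stop_patience = 10L, plateau_patience = 2L,
                     plateau_factor = 0.5, seed = 4L)
  # an absurd learning rate stalls improvement, forcing scheduler action
  tr <- try(train_csae(ae0, fx$segs$source_train, fx$segs$source_val, tc), silent = TRUE)
  if (inherits(tr, "try-error")) {
    expect_match(attr(tr, "condition")$message, "diverged")
  } else {
    expect_lt(min(tr$history$lr), 5)
  }
})
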