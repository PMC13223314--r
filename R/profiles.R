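#' Desk-scale model and training profile
#'
#' The architecture and training settings used throughout the package's
#' desk-scale experiments (1 kHz cohorts, 250-sample windows): a compact
#' autoencoder (16/16 filters, kernels 9/5/3, strides 5/2, 16 latent
#' filters, so T' = 25), a matching head (32 conv filters with kernel 5 —
#' the burst dynamics of the reference cohorts span several latent steps at
#' this resolution — attention width 16, MLP 64/32), and AdamW schedules
#' sized for a single-CPU budget. Full-scale defaults live in
#' [csae_config()] / [classifier_config()].
#'
#' @param seed Base seed recorded in the configs (per-fold seeds are derived
#'   inside [run_loso()]).
#' @return Named list: `csae_cfg`, `clf_cfg`, `tc_csae`, `tc_clf`, `tc_ft`,
#'   `tc_phase1`, `tc_phase2`.
#' @export
desk_profile <- function(seed = 1L) {
  list(
    csae_cfg = csae_config(
      enc_filters = c(16L, 16L), enc_kernels = c(9L, 5L, 3L),
      enc_strides = c(5L, 2L), latent_filters = 16L,
      l1_coeff = 1e-7, seed = seed
    ),
    clf_cfg = classifier_config(
      head_conv_filters = 32L, head_conv_kernel = 5L, attention_dim = 16L,
      mlp_dims = c(64L, 32L), n_classes = 6L, seed = seed
    ),
    tc_csae = train_config(batch_size = 128L, max_epochs = 30L,
                           learning_rate = 2e-3, early_stop_patience = 8L,
                           plateau_patience = 4L, seed = seed),
    tc_clf = train_config(batch_size = 128L, max_epochs = 60L,
                          learning_rate = 2e-3, early_stop_patience = 10L,
                          plateau_patience = 5L, seed = seed),
    tc_ft = train_config(batch_size = 128L, max_epochs = 60L,
                         learning_rate = 1e-3, early_stop_patience = 10L,
                         plateau_patience = 5L, seed = seed),
    tc_phase1 = train_config(batch_size = 128L, max_epochs = 40L,
                             learning_rate = 2e-3, early_stop_patience = 8L,
                             plateau_patience = 4L, seed = seed),
    tc_phase2 = train_config(batch_size = 128L, max_epochs = 40L,
                             learning_rate = 2e-4, early_stop_patience = 8L,
                             plateau_patience = 4L, seed = seed),
    fcae_hidden = c(128L, 32L),
    fcae_bottleneck = 16L,
    cnn_cfg = cnn_lstm_config(conv_filters = c(16L, 16L),
                              conv_kernels = c(9L, 5L),
                              conv_strides = c(5L, 2L), hidden = 24L,
                              seed = seed)
  )
}
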