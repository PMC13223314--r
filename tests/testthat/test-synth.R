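test_that("cohort generation is deterministic and order-independent", {
  cfg <- tiny_cohort_config(9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_length(a, cfg$n_subjects * cfg$n_gestures * cfg$n_trials)

  # a recording's content does not depend on how much of the cohort is made:
  # the same (subject, gesture, trial) from a larger cohort is identical
  cfg_small <- cfg
  cfg_small$n_gestures <- 2L
  cfg_small$envelopes <- cfg$envelopes[1:2]
  small <- generate_cohort(cfg_small)
  pick <- function(coh, s, g, tr) {
    Filter(function(r) r$subject_id == s && r$gesture_id == g && r$trial_id == tr, coh)[[1L]]
  }
  expect_identical(pick(small, "S2", "G02", 3L)$samples,
                   pick(a, "S2", "G02", 3L)$samples)
})

test_that("zero subject shift makes subjects statistically identical by construction", {
  cfg <- tiny_cohort_config(10L)
  cfg$subject_shift_scale <- 0
  coh <- generate_cohort(cfg)
  # same gesture/trial across subjects: identical envelopes and unit gains, so
  # per-channel sd should agree closely (carriers differ per subject)
  sd_of <- function(r) apply(r$samples, 2, sd)
  g1 <- Filter(function(r) r$gesture_id == "G01" & r$trial_id == 1L, coh)
  sds <- vapply(g1, sd_of, numeric(2))
  expect_lt(max(abs(sds[1, ] - mean(sds[1, ]))), 0.2 * mean(sds[1, ]))
})

test_that("fresh carriers give trial-to-trial variability", {
  coh <- generate_cohort(tiny_cohort_config(11L))
  r1 <- coh[[1L]]; r2 <- coh[[2L]]
  expect_equal(r1$gesture_id, r2$gesture_id)
  expect_gt(max(abs(r1$samples - r2$samples)), 0.1)
})

test_that("carrier spectrum keeps at least 95% of power inside the band", {
  cfg <- tiny_cohort_config(12L)
  coh <- generate_cohort(cfg)
  x <- coh[[1L]]$samples[, 1L]
  sp <- Mod(fft(x))^2
  fr <- (seq_along(x) - 1) * cfg$fs / length(x)
  fr <- pmin(fr, cfg$fs - fr)
  lo <- cfg$carrier_band[1L]; hi <- cfg$carrier_band[2L]
  inband <- sum(sp[fr >= lo * 0.85 & fr <= hi * 1.15]) / sum(sp)
  # noise_floor contributes broadband power; with amplitude 0.05 it is < 1%
  expect_gt(inband, 0.95)
})

test_that("amplitude envelopes order mean rectified amplitude as designed", {
  # two gestures, disjoint channel activation, no noise
  env <- list(
    list(envelope_profile(c(0, 1), c(1, 1)), envelope_profile(c(0, 1), c(0.05, 0.05))),
    list(envelope_profile(c(0, 1), c(0.05, 0.05)), envelope_profile(c(0, 1), c(1, 1)))
  )
  cfg <- synth_config(n_subjects = 1L, n_gestures = 2L, n_trials = 1L, fs = 500,
                      trial_duration_s = 1, carrier_band = c(20, 120),
                      envelopes = env, subject_shift_scale = 0,
                      noise_floor = 0, seed = 3L)
  coh <- generate_cohort(cfg)
  mav <- t(vapply(coh, function(r) colMeans(abs(r$samples)), numeric(2)))
  expect_gt(mav[1L, 1L], mav[1L, 2L] * 5)
  expect_gt(mav[2L, 2L], mav[2L, 1L] * 5)
})

test_that("stronger subject shift does not improve cross-subject generalization", {
  # fast probe classifier (time-domain features + random forest) trained on
  # source subjects, tested on the held-out subject, over 3 seeds
  xsub_f1 <- function(shift, sd) {
    cfg <- tiny_cohort_config(sd, n_subjects = 3L)
    cfg$subject_shift_scale <- shift
    cohort <- generate_cohort(cfg)
    plans <- make_loso_folds(cohort)
    segs <- fold_segments(cohort, plans[[1L]], 200, 100)
    scaler <- fit_scaler(segs$source_train)
    segs <- lapply(segs, apply_scaler, stats = scaler)
    rf <- train_rf_baseline(classical_features(segs$source_train),
                            segs$source_train$labels, ntree = 100L, seed = sd)
    mean(predict(rf, classical_features(segs$target_test)) == segs$target_test$labels)
  }
  lo <- mean(vapply(1:3, function(sd) xsub_f1(0, sd), numeric(1)))
  hi <- mean(vapply(1:3, function(sd) xsub_f1(1.0, sd), numeric(1)))
  expect_lte(hi, lo)
})

test_that("reference presets have the documented shapes", {
  e6 <- reference_cohorts("easy6", seed = 1L)
  expect_equal(e6$n_subjects, 8L)
  expect_equal(e6$n_gestures, 6L)
  expect_equal(e6$n_trials, 6L)
  expect_equal(e6$fs, 4000)
  expect_equal(e6$trial_duration_s, 5)

  s6 <- reference_cohorts("shifted6", seed = 1L)
  expect_gt(s6$subject_shift_scale, e6$subject_shift_scale)

  e10 <- reference_cohorts("easy10", seed = 1L)
  expect_equal(e10$n_gestures, 10L)
  # combined gestures superimpose two base profiles, clipped at 1
  expect_s3_class(e10$envelopes[[7L]][[1L]], "semg_envelope_sum")
  t_eval <- seq(0, 1, by = 1e-3)
  v_comb <- csaemg:::eval_envelope(e10$envelopes[[7L]][[1L]], t_eval, 1)
  v_a <- csaemg:::eval_envelope(e10$envelopes[[2L]][[1L]], t_eval, 1)
  v_b <- csaemg:::eval_envelope(e10$envelopes[[3L]][[1L]], t_eval, 1)
  expect_equal(v_comb, pmin(v_a + v_b, 1), tolerance = 1e-12)
  expect_true(all(v_comb <= 1))
})

test_that("temporal2 classes match in amplitude distribution but differ in temporal order", {
  cfg <- reference_cohorts("temporal2", seed = 4L, reduced = TRUE)
  coh <- generate_cohort(cfg)
  g1 <- Filter(function(r) r$gesture_id == "G01", coh)
  g2 <- Filter(function(r) r$gesture_id == "G02", coh)
  a <- abs(unlist(lapply(g1[1:4], function(r) r$samples[, 1L])))
  b <- abs(unlist(lapply(g2[1:4], function(r) r$samples[, 1L])))
  ks <- suppressWarnings(stats::ks.test(sample(a, 3000), sample(b, 3000)))
  expect_lt(unname(ks$statistic), 0.05) # pooled amplitude histograms agree

  # envelope profiles are time reversals of each other: rectified-amplitude
  # autocovariance agrees, but cross-correlation of the envelope against a
  # rising ramp peaks with opposite slope sign
  env_shape <- function(recs) {
    m <- rowMeans(vapply(recs, function(r) abs(r$samples[, 1L]), numeric(nrow(recs[[1]]$samples))))
    stats::filter(m, rep(1 / 25, 25), sides = 2)
  }
  s1 <- env_shape(g1); s2 <- env_shape(g2)
  idx <- 100:1100
  ramp <- seq_along(idx)
  expect_gt(abs(cor(s1[idx], s2[idx]) - 1), 0.05) # shapes differ in time
})
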