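test_that("segmentation follows the closed-form window count and geometry", {
  rec <- tiny_recording(L = 20000L, C = 2L, fs = 4000)
  b <- segment_recording(rec, 250, 125)
  expect_equal(dim(b$segments), c(39L, 1000L, 2L)) # floor((20000-1000)/500)+1

  # segment i starts at sample i * stride (0-based), no padding or wraparound
  expect_identical(b$segments[1L, , ], rec$samples[1:1000, ])
  expect_identical(b$segments[3L, , ], rec$samples[1001:2000, ])
  expect_identical(b$segments[39L, , ], rec$samples[19001:20000, ])

  # exactly one full window
  rec1 <- tiny_recording(L = 1000L, fs = 4000)
  expect_equal(dim(segment_recording(rec1, 250, 125)$segments)[1L], 1L)

  # incomplete tail dropped
  rec2 <- tiny_recording(L = 1250L, fs = 4000)
  expect_equal(dim(segment_recording(rec2, 250, 125)$segments)[1L], 1L)
})

test_that("segment count matches floor((L-T)/S)+1 over random geometries", {
  set.seed(42)
  for (i in 1:25) {
    T_w <- sample(5:50, 1)
    L <- T_w + sample(0:200, 1)
    S_w <- sample(1:T_w, 1)
    rec <- new_recording("S", "G", 1L, matrix(rnorm(L), ncol = 1), fs = 1000)
    b <- segment_recording(rec, T_w, S_w) # ms == samples at 1 kHz
    expect_equal(dim(b$segments)[1L], (L - T_w) %/% S_w + 1L)
    # last window stays inside the recording
    n_seg <- dim(b$segments)[1L]
    expect_lte((n_seg - 1L) * S_w + T_w, L)
  }
})

test_that("segmentation rejects invalid geometry", {
  rec <- tiny_recording(L = 500L, fs = 4000)
  expect_error(segment_recording(rec, 250, 125), "longer than the recording")
  expect_error(segment_recording(rec, 100, 0), "positive")
})

test_that("scaler statistics equal a direct whole-batch computation and transform correctly", {
  fx <- tiny_fold(1L)
  raw <- generate_cohort(tiny_cohort_config(1L))
  b <- segment_cohort(raw[1:6], 200, 100)
  st <- fit_scaler(b)
  x <- b$segments
  dim(x) <- c(prod(dim(x)[1:2]), dim(x)[3L])
  expect_equal(st$mean, colMeans(x), tolerance = 1e-12)
  expect_equal(st$sd, apply(x, 2, sd), tolerance = 1e-12)

  # transform of the fit partition is standardized
  z <- apply_scaler(b, st)$segments
  dim(z) <- dim(x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)

  # simple affine check
  const <- new_recording("S", "G", 1L, matrix(4, 100, 1), 1000)
  cb <- segment_recording(const, 50, 50)
  st2 <- structure(list(mean = 2, sd = 2, fitted_on = "x"), class = "semg_scaler")
  expect_true(all(apply_scaler(cb, st2)$segments == 1))
})

test_that("degenerate zero-variance channels get the epsilon floor with a warning", {
  zero <- new_recording("S", "G", 1L, matrix(0, 200, 2), 1000)
  b <- segment_recording(zero, 100, 100)
  expect_warning(st <- fit_scaler(b), "zero-variance")
  expect_equal(st$mean, c(0, 0))
  expect_equal(st$sd, c(1e-8, 1e-8))
})

test_that("scaler rejects channel mismatch", {
  fx <- tiny_fold(1L)
  st <- fit_scaler(fx$segs$source_train)
  one_ch <- segment_recording(new_recording("S", "G", 1L, matrix(rnorm(400), ncol = 1), 500),
                              200, 100)
  expect_error(apply_scaler(one_ch, st), "channel mismatch")
})

test_that("LOSO folds partition subjects and enforce the default trial plan", {
  cohort <- generate_cohort(tiny_cohort_config(2L, n_subjects = 3L))
  plans <- make_loso_folds(cohort)
  expect_length(plans, 3L)
  subjects <- sort(unique(vapply(cohort, `[[`, character(1), "subject_id")))
  targets <- vapply(plans, `[[`, character(1), "target_subject")
  expect_setequal(targets, subjects)
  for (p in plans) {
    expect_false(p$target_subject %in% p$source_subjects)
    expect_setequal(c(p$target_subject, p$source_subjects), subjects)
    expect_equal(p$source_train_trials, 1:4)
    expect_equal(p$source_val_trials, 5L)
    expect_equal(p$source_test_trials, 6L)
    expect_equal(p$target_calib_trials, 1L)
    expect_equal(p$target_val_trials, 2L)
    expect_equal(p$target_test_trials, 3:6)
  }
})

test_that("LOSO construction rejects degenerate cohorts", {
  cohort <- generate_cohort(tiny_cohort_config(3L, n_subjects = 1L))
  expect_error(make_loso_folds(cohort), "at least 2 subjects")
  short <- generate_cohort(tiny_cohort_config(4L, n_trials = 4L))
  expect_error(make_loso_folds(short), "missing trial")
})

test_that("leakage guard rejects plans sharing trials across partitions", {
  plans <- make_loso_folds(generate_cohort(tiny_cohort_config(5L)))
  bad <- plans[[1L]]
  bad$source_test_trials <- c(4L, 6L) # trial 4 is also in training
  expect_error(assert_split_plan(bad), "leakage")
  bad2 <- plans[[1L]]
  bad2$source_subjects <- c(bad2$source_subjects, bad2$target_subject)
  expect_error(assert_split_plan(bad2), "leakage")
})

test_that("fold segments carry provenance consistent with the plan", {
  fx <- tiny_fold(1L)
  p <- fx$plan
  s <- fx$segs
  expect_true(all(s$source_train$subject_ids %in% p$source_subjects))
  expect_true(all(s$source_train$trial_ids %in% p$source_train_trials))
  expect_true(all(s$target_test$subject_ids == p$target_subject))
  expect_true(all(s$target_test$trial_ids %in% p$target_test_trials))
  # no (subject, trial) overlap between train-side and test partitions
  key <- function(b) paste(b$subject_ids, b$trial_ids)
  expect_length(intersect(key(s$source_train), key(s$source_test)), 0L)
  expect_length(intersect(key(s$source_train), key(s$target_test)), 0L)
})

test_that("one-hot encoding follows the ordered class list", {
  y <- one_hot(c("b", "a", "b"), c("a", "b", "c"))
  expect_equal(dim(y), c(3L, 3L))
  expect_equal(y[, "a"], c(0, 1, 0))
  expect_equal(y[, "b"], c(1, 0, 1))
  expect_error(one_hot("d", c("a", "b")), "outside")
})
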