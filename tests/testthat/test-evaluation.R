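test_that("precision/recall/F1 match direct formulas and a brute-force counting oracle", {
  # one-vs-rest anchor: TP=8, FP=2, FN=2 -> P = R = F1 = 0.8
  y_true <- c(rep("a", 10), rep("b", 12))
  y_pred <- c(rep("a", 8), "b", "b", rep("b", 10), "a", "a")
  m <- prf1(y_true, y_pred, c("a", "b"))
  row_a <- m$per_class[m$per_class$class == "a", ]
  expect_equal(row_a$precision, 0.8)
  expect_equal(row_a$recall, 0.8)
  expect_equal(row_a$f1, 0.8)

  # perfect predictions
  mp <- prf1(y_true, y_true, c("a", "b"))
  expect_true(all(mp$per_class$f1 == 1))
  expect_equal(unname(mp$micro["f1"]), 1)
  expect_true(all(mp$confusion[upper.tri(mp$confusion)] == 0))

  # random multi-class case vs an exhaustive per-pair counting oracle
  set.seed(99)
  classes <- c("x", "y", "z")
  for (rep_i in 1:5) {
    yt <- sample(classes, 60, replace = TRUE)
    yp <- sample(classes, 60, replace = TRUE)
    got <- prf1(yt, yp, classes)
    for (cl in classes) {
      tp <- sum(yt == cl & yp == cl)
      fp <- sum(yt != cl & yp == cl)
      fn <- sum(yt == cl & yp != cl)
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
      row <- got$per_class[got$per_class$class == cl, ]
      expect_equal(row$precision, p)
      expect_equal(row$recall, r)
      expect_equal(row$f1, f1)
    }
    # micro-F1 equals accuracy in single-label multi-class prediction
    expect_equal(unname(got$micro["f1"]), mean(yt == yp), tolerance = 1e-12)
    expect_equal(sum(got$confusion), 60)
  }
  expect_error(prf1(character(0), character(0), classes), "empty")
})

test_that("per-class metrics are invariant to class-list ordering", {
  set.seed(7)
  yt <- sample(c("a", "b", "c"), 40, replace = TRUE)
  yp <- sample(c("a", "b", "c"), 40, replace = TRUE)
  m1 <- prf1(yt, yp, c("a", "b", "c"))$per_class
  m2 <- prf1(yt, yp, c("c", "a", "b"))$per_class
  m2 <- m2[match(m1$class, m2$class), ]
  expect_equal(m1$f1, m2$f1)
  expect_equal(m1$precision, m2$precision)
})

test_that("zero-division cases yield 0 with the flag set", {
  m <- prf1(c("a", "a", "b"), c("b", "b", "b"), c("a", "b", "c"))
  row_a <- m$per_class[m$per_class$class == "a", ]
  expect_equal(row_a$f1, 0)
  expect_true(row_a$zero_division)
  row_c <- m$per_class[m$per_class$class == "c", ]
  expect_equal(row_c$precision, 0)
  expect_true(row_c$zero_division)
})

test_that("confusion flow fractions match brute-force counts and flag undefined cases", {
  yt <- c(rep("a", 6), rep("b", 4))
  yp <- c("a", "b", "b", "b", "c", "c", rep("b", 4))
  m <- prf1(yt, yp, c("a", "b", "c"))
  expect_equal(confusion_flow(m, "a", "b"), 3 / 5)
  expect_equal(confusion_flow(m, "a", "c"), 2 / 5)
  flow_b <- confusion_flow(m, "b", "a")
  expect_true(is.na(flow_b))
  expect_match(attr(flow_b, "note"), "no misclassified")

  # all errors to one class -> 1; split evenly over three -> 1/3
  m2 <- prf1(c("a", "a", "a", "a"), c("a", "b", "b", "b"), c("a", "b"))
  expect_equal(confusion_flow(m2, "a", "b"), 1)
  m3 <- prf1(rep("a", 6), c("b", "c", "d", "b", "c", "d"), c("a", "b", "c", "d"))
  expect_equal(confusion_flow(m3, "a", "c"), 1 / 3)
})

test_that("cross-fold aggregation computes mean and standard error correctly", {
  mk <- function(f1_target) {
    # craft predictions with a known accuracy
    n <- 20L
    correct <- round(f1_target * n)
    yt <- rep(c("a", "b"), each = n / 2)
    yp <- yt
    if (correct < n) yp[seq_len(n - correct)] <- ifelse(yt[seq_len(n - correct)] == "a", "b", "a")
    prf1(yt, yp, c("a", "b"))
  }
  r <- cv_report(list(mk(0.8), mk(0.9), mk(1.0)))
  scores <- r$micro_f1_per_fold
  expect_equal(unname(r$micro_f1["mean"]), mean(scores))
  expect_equal(unname(r$micro_f1["se"]), sd(scores) / sqrt(3), tolerance = 1e-12)
  # identical per-fold scores give SE = 0
  r0 <- cv_report(list(mk(0.9), mk(0.9)))
  expect_equal(unname(r0$micro_f1["se"]), 0)
})

test_that("a two-subject pooled LOSO run returns a structurally complete report", {
  cohort <- generate_cohort(tiny_cohort_config(21L))
  pf <- list(
    csae = toy_csae_config(1L), clf = toy_clf_config(3L),
    tc = fast_tc(2L)
  )
  res <- run_loso(cohort, "pooled", pf$csae, pf$clf, pf$tc, pf$tc,
                  window_ms = 200, stride_ms = 100, seed = 5L)
  expect_s3_class(res, "semg_loso_result")
  expect_length(res$folds, 2L)
  expect_true(is.finite(res$pooled$micro_f1["mean"]))
  expect_gte(res$pooled$micro_f1["se"], 0)
  expect_true(is.finite(res$r2))
  # per-fold seeds derive deterministically from the global seed
  res2 <- run_loso(cohort, "pooled", pf$csae, pf$clf, pf$tc, pf$tc,
                   window_ms = 200, stride_ms = 100, seed = 5L)
  expect_identical(res$pooled$micro_f1, res2$pooled$micro_f1)
})

test_that("lambda sweep emits one row per grid point and reports the argmax", {
  cohort <- generate_cohort(tiny_cohort_config(22L))
  tab <- lambda_sweep(cohort, c(0, 1e-4), c(3L, 4L),
                      csae_cfg = toy_csae_config(), clf_cfg = toy_clf_config(3L),
                      tc_csae = fast_tc(2L), tc_clf = fast_tc(2L),
                      window_ms = 200, stride_ms = 100, folds = 1L, seed = 6L)
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$is_argmax), 1L)
  expect_true(all(tab$sparsity >= 0 & tab$sparsity <= 1))
  single <- lambda_sweep(cohort, 1e-7, 3L,
                         csae_cfg = toy_csae_config(), clf_cfg = toy_clf_config(3L),
                         tc_csae = fast_tc(1L), tc_clf = fast_tc(1L),
                         window_ms = 200, stride_ms = 100, folds = 1L, seed = 6L)
  expect_equal(nrow(single), 1L)
})
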