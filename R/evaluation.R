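# Metrics and leave-one-subject-out orchestration -----------------------------

#' Precision / recall / F1 report
#'
#' One-vs-rest per class: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`; a zero denominator yields 0 with the `zero_division`
#' flag set. The micro average pools TP/FP/FN over classes, which for
#' single-label multi-class prediction makes micro-F1 equal to accuracy.
#'
#' @param y_true,y_pred Character vectors of true and predicted classes.
#' @param class_list Ordered class list; both label vectors must lie in it.
#' @return An `semg_metrics`: `confusion` (K x K, true in rows), `per_class`
#'   data.frame, `micro` (P/R/F1), `accuracy`, `n`.
#' @export
prf1 <- function(y_true, y_pred, class_list) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(y_true) == length(y_pred))
  class_list <- as.character(class_list)
  check_labels(y_true, class_list)
  check_labels(y_pred, class_list)
  cm <- table(
    factor(y_true, levels = class_list),
    factor(y_pred, levels = class_list)
  )
  cm <- unclass(as.matrix(cm))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  per_class <- data.frame(
    class = class_list, tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), precision = as.numeric(p), recall = as.numeric(r),
    f1 = as.numeric(f1),
    zero_division = (tp + fp == 0) | (tp + fn == 0) | (p + r == 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tp_s <- sum(tp); fp_s <- sum(fp); fn_s <- sum(fn)
  micro_p <- safe_div(tp_s, tp_s + fp_s)
  micro_r <- safe_div(tp_s, tp_s + fn_s)
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      micro = c(precision = micro_p, recall = micro_r,
                f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r)),
      accuracy = tp_s / length(y_true),
      n = length(y_true)
    ),
    class = "semg_metrics"
  )
}

#' @export
print.semg_metrics <- function(x, ...) {
  cat(sprintf("<semg_metrics> n = %d, micro-F1 = %.4f (accuracy %.4f)\n",
              x$n, x$micro["f1"], x$accuracy))
  print(x$per_class[, c("class", "precision", "recall", "f1")], digits = 3)
  invisible(x)
}

#' Fraction of one class's errors captured by another class
#'
#' `count(true = a, pred = b) / count(true = a, pred != a)`. Undefined (NA,
#' with a message attribute) when class `a` has no misclassified instances.
#'
#' @param report An `semg_metrics`.
#' @param class_a True class whose errors are analyzed.
#' @param class_b Predicted class receiving them.
#' @return Scalar fraction, or NA if `a` has no errors.
#' @export
confusion_flow <- function(report, class_a, class_b) {
  stopifnot(inherits(report, "semg_metrics"))
  cm <- report$confusion
  stopifnot(class_a %in% rownames(cm), class_b %in% colnames(cm))
  errs <- sum(cm[class_a, ]) - cm[class_a, class_a]
  if (errs == 0) {
    out <- NA_real_
    attr(out, "note") <- sprintf("class %s has no misclassified instances", class_a)
    return(out)
  }
  unname(cm[class_a, class_b] / errs)
}

# cross-fold mean and standard error (sd / sqrt(n_folds))
mean_se <- function(x) {
  n <- length(x)
  c(mean = mean(x), se = if (n > 1L) stats::sd(x) / sqrt(n) else 0)
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' @param fold_metrics List of `semg_metrics`, one per fold.
#' @return An `semg_cv_report` with per-fold reports, the cross-fold mean
#'   and standard error of micro-F1, and per-class F1 mean/SE.
#' @export
cv_report <- function(fold_metrics) {
  stopifnot(length(fold_metrics) >= 1L)
  micro <- vapply(fold_metrics, function(m) unname(m$micro["f1"]), numeric(1))
  classes <- fold_metrics[[1L]]$per_class$class
  per_class_f1 <- sapply(classes, function(cl) {
    vapply(fold_metrics, function(m) m$per_class$f1[m$per_class$class == cl], numeric(1))
  })
  per_class_f1 <- matrix(per_class_f1, nrow = length(fold_metrics),
                         dimnames = list(NULL, classes))
  pc <- apply(per_class_f1, 2L, mean_se)
  structure(
    list(
      folds = fold_metrics,
      micro_f1 = mean_se(micro),
      micro_f1_per_fold = micro,
      per_class_f1 = data.frame(class = classes, mean = pc["mean", ],
                                se = pc["se", ], row.names = NULL,
                                stringsAsFactors = FALSE)
    ),
    class = "semg_cv_report"
  )
}

#' @export
print.semg_cv_report <- function(x, ...) {
  cat(sprintf("<semg_cv_report> %d folds: micro-F1 %.4f +/- %.4f (SE)\n",
              length(x$folds), x$micro_f1["mean"], x$micro_f1["se"]))
  invisible(x)
}

# one fold of the pooled / adapt protocols; returns trained models + metrics
run_fold <- function(cohort, plan, fold_seed, protocol, csae_cfg, clf_cfg,
                     tc_csae, tc_clf, tc_ft, window_ms, stride_ms) {
  segs <- fold_segments(cohort, plan, window_ms, stride_ms)
  scaler <- fit_scaler(segs$source_train,
                       fitted_on = sprintf("source-train (target %s held out)",
                                           plan$target_subject))
  segs <- lapply(segs, apply_scaler, stats = scaler)
  class_list <- sort(unique(segs$source_train$labels))

  t_len <- dim(segs$source_train$segments)[2L]
  c_ch <- dim(segs$source_train$segments)[3L]
  csae_cfg$seed <- substream_seed(fold_seed, "csae")
  ae <- build_csae(csae_cfg, c(t_len, c_ch))
  tc_ae <- tc_csae; tc_ae$seed <- substream_seed(fold_seed, "csae-train")
  ae <- train_csae(ae, segs$source_train, segs$source_val, tc_ae)

  clf_cfg$seed <- substream_seed(fold_seed, "clf")
  clf_cfg$n_classes <- length(class_list)
  clf <- build_classifier(ae, clf_cfg, class_list)
  tc_cl <- tc_clf; tc_cl$seed <- substream_seed(fold_seed, "clf-train")
  clf <- train_classifier(clf, segs$source_train, segs$source_val, tc_cl)

  out <- list(
    plan = plan, scaler = scaler, csae = ae, classifier = clf,
    pooled = prf1(segs$source_test$labels,
                  predict(clf, segs$source_test)$labels, class_list),
    r2_test = r2_reconstruction(ae, segs$source_test)
  )
  if (protocol == "adapt") {
    out$target_pre <- prf1(segs$target_test$labels,
                           predict(clf, segs$target_test)$labels, class_list)
    tc_f <- tc_ft; tc_f$seed <- substream_seed(fold_seed, "finetune")
    tuned <- few_shot_finetune(clf, segs$target_calib, segs$target_val, tc_f)
    out$target_post <- prf1(segs$target_test$labels,
                            predict(tuned, segs$target_test)$labels, class_list)
    out$tuned <- tuned
  }
  out
}

# one fold of the expansion protocol: 6-class training, decapitation + weight
# transfer, two-phase 10-class training, forgetting analysis
run_fold_expand <- function(cohort, plan, fold_seed, csae_cfg, clf_cfg,
                            tc_csae, tc_clf, tc1, tc2, n_base,
                            window_ms, stride_ms) {
  segs <- fold_segments(cohort, plan, window_ms, stride_ms)
  all_classes <- sort(unique(segs$source_train$labels))
  stopifnot(length(all_classes) > n_base)
  base_classes <- all_classes[seq_len(n_base)]
  pick <- function(b, classes) subset_segments(b, b$labels %in% classes)
  segs6 <- lapply(segs, pick, classes = base_classes)

  # scaler and feature extractor come from the base-class training data and
  # are reused unchanged for the expanded set
  scaler <- fit_scaler(segs6$source_train, fitted_on = "base-class source-train")
  segs <- lapply(segs, apply_scaler, stats = scaler)
  segs6 <- lapply(segs6, apply_scaler, stats = scaler)

  t_len <- dim(segs$source_train$segments)[2L]
  c_ch <- dim(segs$source_train$segments)[3L]
  csae_cfg$seed <- substream_seed(fold_seed, "csae")
  ae <- build_csae(csae_cfg, c(t_len, c_ch))
  tc_ae <- tc_csae; tc_ae$seed <- substream_seed(fold_seed, "csae-train")
  ae <- train_csae(ae, segs6$source_train, segs6$source_val, tc_ae)

  clf_cfg$seed <- substream_seed(fold_seed, "clf")
  clf_cfg$n_classes <- length(base_classes)
  clf6 <- build_classifier(ae, clf_cfg, base_classes)
  tc_cl <- tc_clf; tc_cl$seed <- substream_seed(fold_seed, "clf-train")
  clf6 <- train_classifier(clf6, segs6$source_train, segs6$source_val, tc_cl)

  wide <- expand_classes(clf6, all_classes, seed = substream_seed(fold_seed, "expand"))
  tcp1 <- tc1; tcp1$seed <- substream_seed(fold_seed, "phase1")
  tcp2 <- tc2; tcp2$seed <- substream_seed(fold_seed, "phase2")
  tp <- two_phase_train(wide, segs$source_train, segs$source_val, tcp1, tcp2)

  list(
    plan = plan, scaler = scaler, csae = ae, classifier6 = clf6,
    classifier10 = tp$model,
    phase1 = prf1(segs$source_test$labels,
                  predict(tp$phase1_model, segs$source_test)$labels, all_classes),
    phase2 = prf1(segs$source_test$labels,
                  predict(tp$model, segs$source_test)$labels, all_classes),
    base6 = prf1(segs6$source_test$labels,
                 predict(clf6, segs6$source_test)$labels, base_classes),
    forgetting = forgetting_report(clf6, tp$model, segs6$source_test)
  )
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For each fold: fit the scaler on the source-domain training trials, train
#' the autoencoder unsupervised on the same partition, train the classifier
#' head, then evaluate according to the protocol:
#' \describe{
#'   \item{pooled}{closed-set performance on the source-domain held-out
#'     trial; also reports held-out reconstruction R-squared.}
#'   \item{adapt}{additionally scores the unseen target subject before and
#'     after few-shot calibration on its calibration/validation trials.}
#'   \item{expand}{trains the base-class model on the first `n_base_classes`
#'     classes, expands the output layer to the full class set with weight
#'     transfer, runs the two-phase protocol, and reports Phase I / Phase II
#'     metrics plus a forgetting report.}
#' }
#'
#' @param cohort List of `semg_recording`s.
#' @param protocol One of `"pooled"`, `"adapt"`, `"expand"`.
#' @param csae_cfg,clf_cfg Model configurations (fold seeds are derived from
#'   `seed` deterministically; the seeds inside these configs are ignored).
#' @param tc_csae,tc_clf Training configurations.
#' @param tc_ft Fine-tuning configuration (adapt protocol).
#' @param tc_phase1,tc_phase2 Two-phase configurations (expand protocol).
#' @param n_base_classes Size of the base class set for `expand`.
#' @param window_ms,stride_ms Segmentation geometry.
#' @param folds Optional integer subset of folds to run (default all).
#' @param seed Global seed; per-fold seeds derive from it.
#' @return An `semg_loso_result`: per-fold results plus `semg_cv_report`s
#'   (`pooled`, and per protocol `target_pre`/`target_post` or
#'   `phase1`/`phase2`), and mean held-out reconstruction R-squared where
#'   applicable.
#' @export
run_loso <- function(cohort, protocol = c("pooled", "adapt", "expand"),
                     csae_cfg = csae_config(), clf_cfg = classifier_config(),
                     tc_csae = train_config(), tc_clf = train_config(),
                     tc_ft = train_config(),
                     tc_phase1 = train_config(),
                     tc_phase2 = train_config(learning_rate = tc_phase1$learning_rate * 0.1),
                     n_base_classes = 6L,
                     window_ms = 250, stride_ms = 125,
                     folds = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  plans <- make_loso_folds(cohort)
  if (is.null(folds)) folds <- seq_along(plans)
  stopifnot(all(folds >= 1L), all(folds <= length(plans)))
  results <- vector("list", length(folds))
  for (j in seq_along(folds)) {
    i <- folds[j]
    fold_seed <- substream_seed(seed, paste0("fold:", i))
    results[[j]] <- if (protocol == "expand") {
      run_fold_expand(cohort, plans[[i]], fold_seed, csae_cfg, clf_cfg,
                      tc_csae, tc_clf, tc_phase1, tc_phase2, n_base_classes,
                      window_ms, stride_ms)
    } else {
      run_fold(cohort, plans[[i]], fold_seed, protocol, csae_cfg, clf_cfg,
               tc_csae, tc_clf, tc_ft, window_ms, stride_ms)
    }
  }
  out <- list(protocol = protocol, folds = results, fold_indices = folds, seed = seed)
  if (protocol == "expand") {
    out$phase1 <- cv_report(lapply(results, `[[`, "phase1"))
    out$phase2 <- cv_report(lapply(results, `[[`, "phase2"))
    out$base6 <- cv_report(lapply(results, `[[`, "base6"))
  } else {
    out$pooled <- cv_report(lapply(results, `[[`, "pooled"))
    out$r2 <- mean(vapply(results, `[[`, numeric(1), "r2_test"))
    if (protocol == "adapt") {
      out$target_pre <- cv_report(lapply(results, `[[`, "target_pre"))
      out$target_post <- cv_report(lapply(results, `[[`, "target_post"))
    }
  }
  structure(out, class = "semg_loso_result")
}

#' @export
print.semg_loso_result <- function(x, ...) {
  cat(sprintf("<semg_loso_result> protocol '%s', %d fold(s)\n",
              x$protocol, length(x$folds)))
  show <- function(lbl, r) {
    cat(sprintf("  %-12s micro-F1 %.4f +/- %.4f\n", lbl,
                r$micro_f1["mean"], r$micro_f1["se"]))
  }
  if (!is.null(x$pooled)) show("pooled", x$pooled)
  if (!is.null(x$r2)) cat(sprintf("  %-12s %.4f\n", "test R2", x$r2))
  if (!is.null(x$target_pre)) show("target pre", x$target_pre)
  if (!is.null(x$target_post)) show("target post", x$target_post)
  if (!is.null(x$phase1)) show("phase I", x$phase1)
  if (!is.null(x$phase2)) show("phase II", x$phase2)
  invisible(x)
}

#' Sweep the sparsity coefficient and bottleneck width
#'
#' For every (lambda, D) grid point, trains the autoencoder and classifier
#' under the pooled protocol and records mean micro-F1 plus the fraction of
#' near-zero bottleneck activations on the held-out trial. The grid argmax
#' by mean F1 is flagged.
#'
#' @param cohort List of `semg_recording`s.
#' @param lambda_grid Numeric vector of L1 coefficients.
#' @param filter_grid Integer vector of bottleneck filter counts `D`.
#' @inheritParams run_loso
#' @param sparsity_thresh Magnitude below which an activation counts as zero.
#' @return data.frame with one row per grid point: `lambda`, `latent_filters`,
#'   `mean_f1`, `se_f1`, `sparsity`, `is_argmax`.
#' @export
lambda_sweep <- function(cohort, lambda_grid, filter_grid,
                         csae_cfg = csae_config(), clf_cfg = classifier_config(),
                         tc_csae = train_config(), tc_clf = train_config(),
                         window_ms = 250, stride_ms = 125,
                         folds = NULL, seed = 1L, sparsity_thresh = 1e-3) {
  stopifnot(length(lambda_grid) >= 1L, length(filter_grid) >= 1L)
  grid <- expand.grid(lambda = lambda_grid, latent_filters = filter_grid)
  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    cfg <- csae_cfg
    cfg$l1_coeff <- grid$lambda[gi]
    cfg$latent_filters <- as.integer(grid$latent_filters[gi])
    res <- run_loso(cohort, "pooled", cfg, clf_cfg, tc_csae, tc_clf,
                    window_ms = window_ms, stride_ms = stride_ms,
                    folds = folds, seed = seed)
    spars <- mean(vapply(res$folds, function(f) {
      segs <- fold_segments(cohort, f$plan, window_ms, stride_ms)
      test <- apply_scaler(segs$source_test, f$scaler)
      latent_sparsity(f$csae, test, sparsity_thresh)
    }, numeric(1)))
    data.frame(lambda = grid$lambda[gi], latent_filters = grid$latent_filters[gi],
               mean_f1 = unname(res$pooled$micro_f1["mean"]),
               se_f1 = unname(res$pooled$micro_f1["se"]),
               sparsity = spars)
  })
  out <- do.call(rbind, rows)
  out$is_argmax <- seq_len(nrow(out)) == which.max(out$mean_f1)
  out
}
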