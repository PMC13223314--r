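#' Construct an sEMG recording
#'
#' A recording is one continuous multichannel voltage trace for a single
#' (subject, gesture, trial) combination, together with its sampling rate.
#' All recordings in a cohort are expected to share the channel count and
#' sampling rate; trial lengths may differ.
#'
#' @param subject_id,gesture_id Opaque identifiers (coerced to character).
#' @param trial_id 1-based trial index within the (subject, gesture) pair.
#' @param samples Numeric matrix, L time-samples x C channels.
#' @param fs Sampling rate in Hz.
#' @return An object of class `semg_recording`.
#' @export
new_recording <- function(subject_id, gesture_id, trial_id, samples, fs) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1L || ncol(samples) < 1L) {
    stop("`samples` must be a numeric L x C matrix with L >= 1, C >= 1", call. = FALSE)
  }
  assert_scalar_pos(fs, "fs")
  trial_id <- as.integer(trial_id)
  if (is.na(trial_id) || trial_id < 1L) stop("`trial_id` must be a 1-based integer", call. = FALSE)
  structure(
    list(
      subject_id = as.character(subject_id),
      gesture_id = as.character(gesture_id),
      trial_id = trial_id,
      samples = unname(samples),
      fs = fs
    ),
    class = "semg_recording"
  )
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> subject %s, gesture %s, trial %d: %d samples x %d channels @ %g Hz (%.3f s)\n",
    x$subject_id, x$gesture_id, x$trial_id, nrow(x$samples), ncol(x$samples),
    x$fs, nrow(x$samples) / x$fs
  ))
  invisible(x)
}

new_segment_batch <- function(segments, labels, subject_ids, trial_ids,
                              window_ms, stride_ms, fs) {
  stopifnot(length(dim(segments)) == 3L)
  n <- dim(segments)[1L]
  stopifnot(length(labels) == n, length(subject_ids) == n, length(trial_ids) == n)
  structure(
    list(
      segments = segments,
      labels = as.character(labels),
      subject_ids = as.character(subject_ids),
      trial_ids = as.integer(trial_ids),
      window_ms = window_ms,
      stride_ms = stride_ms,
      fs = fs
    ),
    class = "semg_segments"
  )
}

#' @export
print.semg_segments <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<semg_segments> %d segments of %d samples x %d channels (window %g ms, stride %g ms, %g Hz)\n",
    d[1L], d[2L], d[3L], x$window_ms, x$stride_ms, x$fs
  ))
  cat(sprintf("  classes: %s\n", paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Sliding-window segmentation of a recording
#'
#' Slices a continuous recording into fixed-length windows. With the defaults
#' (250 ms window, 125 ms stride) consecutive windows overlap by 50%, so a
#' classification decision is available every 125 ms while each decision sees
#' a full 250 ms of signal. Any incomplete tail is dropped: every segment has
#' exactly `round(window_ms * fs / 1000)` samples. Segment i (0-based) starts
#' at sample `i * stride_samples` (0-based, half-open window).
#'
#' @param recording A `semg_recording`.
#' @param window_ms Window length in milliseconds.
#' @param stride_ms Advance between consecutive windows, in milliseconds.
#' @return A `semg_segments` batch with one row of provenance per segment.
#' @export
segment_recording <- function(recording, window_ms = 250, stride_ms = 125) {
  stopifnot(inherits(recording, "semg_recording"))
  assert_scalar_pos(window_ms, "window_ms")
  if (!is.numeric(stride_ms) || stride_ms <= 0) {
    stop("`stride_ms` must be positive", call. = FALSE)
  }
  L <- nrow(recording$samples)
  C <- ncol(recording$samples)
  T_w <- as.integer(round(window_ms * recording$fs / 1000))
  S_w <- as.integer(round(stride_ms * recording$fs / 1000))
  if (S_w < 1L) stop("stride is below one sample at this sampling rate", call. = FALSE)
  if (T_w > L) {
    stop(sprintf("window (%d samples) is longer than the recording (%d samples)", T_w, L),
         call. = FALSE)
  }
  n_seg <- (L - T_w) %/% S_w + 1L
  segs <- array(0, dim = c(n_seg, T_w, C))
  for (i in seq_len(n_seg)) {
    start <- (i - 1L) * S_w + 1L
    segs[i, , ] <- recording$samples[start:(start + T_w - 1L), , drop = FALSE]
  }
  new_segment_batch(
    segs,
    labels = rep(recording$gesture_id, n_seg),
    subject_ids = rep(recording$subject_id, n_seg),
    trial_ids = rep(recording$trial_id, n_seg),
    window_ms = window_ms, stride_ms = stride_ms, fs = recording$fs
  )
}

#' Segment every recording in a cohort into one batch
#'
#' @param cohort List of `semg_recording` objects sharing fs and channel count.
#' @inheritParams segment_recording
#' @return A single `semg_segments` batch concatenating all windows.
#' @export
segment_cohort <- function(cohort, window_ms = 250, stride_ms = 125) {
  stopifnot(length(cohort) >= 1L)
  batches <- lapply(cohort, segment_recording, window_ms = window_ms, stride_ms = stride_ms)
  bind_segment_batches(batches)
}

#' Concatenate segment batches
#'
#' @param batches List of `semg_segments` with identical window geometry.
#' @return One combined `semg_segments`.
#' @export
bind_segment_batches <- function(batches) {
  stopifnot(length(batches) >= 1L)
  d <- dim(batches[[1L]]$segments)
  for (b in batches) {
    if (!all(dim(b$segments)[2:3] == d[2:3])) {
      stop("segment batches have incompatible shapes", call. = FALSE)
    }
  }
  n_tot <- sum(vapply(batches, function(b) dim(b$segments)[1L], integer(1)))
  segs <- array(0, dim = c(n_tot, d[2L], d[3L]))
  at <- 0L
  for (b in batches) {
    n <- dim(b$segments)[1L]
    if (n > 0L) segs[(at + 1L):(at + n), , ] <- b$segments
    at <- at + n
  }
  new_segment_batch(
    segs,
    labels = unlist(lapply(batches, `[[`, "labels")),
    subject_ids = unlist(lapply(batches, `[[`, "subject_ids")),
    trial_ids = unlist(lapply(batches, `[[`, "trial_ids")),
    window_ms = batches[[1L]]$window_ms,
    stride_ms = batches[[1L]]$stride_ms,
    fs = batches[[1L]]$fs
  )
}

#' Subset a segment batch by index
#' @param batch A `semg_segments`.
#' @param idx Integer or logical index over segments.
#' @return The subset `semg_segments`.
#' @export
subset_segments <- function(batch, idx) {
  new_segment_batch(
    batch$segments[idx, , , drop = FALSE],
    batch$labels[idx], batch$subject_ids[idx], batch$trial_ids[idx],
    batch$window_ms, batch$stride_ms, batch$fs
  )
}

#' Fit a per-channel standardization scaler on training segments
#'
#' Computes the per-channel mean and standard deviation pooled over all
#' time-samples of all training segments. Fitting only on the training
#' partition (and reusing the fitted statistics for validation, test, and
#' target-subject data) prevents information leakage into evaluation.
#' Zero-variance channels are floored at `eps` with a warning.
#'
#' @param train A `semg_segments` from the training partition only.
#' @param eps Standard-deviation floor for degenerate channels.
#' @param fitted_on Free-text description of the fit partition (provenance).
#' @return A `semg_scaler` with fields `mean`, `sd`, `fitted_on`.
#' @export
fit_scaler <- function(train, eps = 1e-8, fitted_on = "train") {
  stopifnot(inherits(train, "semg_segments"))
  d <- dim(train$segments)
  if (d[1L] < 1L) stop("training batch is empty", call. = FALSE)
  x <- train$segments
  dim(x) <- c(d[1L] * d[2L], d[3L])
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  if (any(sdev < eps)) {
    warning(sprintf("zero-variance channel(s) %s: flooring sd at %g",
                    paste(which(sdev < eps), collapse = ","), eps))
    sdev <- pmax(sdev, eps)
  }
  structure(list(mean = mu, sd = sdev, fitted_on = fitted_on), class = "semg_scaler")
}

#' Standardize a segment batch with previously fitted statistics
#'
#' @param batch A `semg_segments`.
#' @param stats A `semg_scaler` from [fit_scaler()].
#' @return The standardized `semg_segments` (per channel, `(x - mean) / sd`).
#' @export
apply_scaler <- function(batch, stats) {
  stopifnot(inherits(batch, "semg_segments"), inherits(stats, "semg_scaler"))
  d <- dim(batch$segments)
  if (d[3L] != length(stats$mean)) {
    stop(sprintf("channel mismatch: batch has %d channels, scaler was fitted on %d",
                 d[3L], length(stats$mean)), call. = FALSE)
  }
  x <- batch$segments
  for (c_i in seq_len(d[3L])) {
    x[, , c_i] <- (x[, , c_i] - stats$mean[c_i]) / stats$sd[c_i]
  }
  out <- batch
  out$segments <- x
  out
}

#' Build leave-one-subject-out split plans
#'
#' One fold per subject: that subject becomes the unseen target domain, all
#' remaining subjects form the source domain. Within the source domain trials
#' are assigned chronologically to train / validation / test; the target
#' subject contributes a minimal calibration trial, a validation trial, and a
#' held-out test block. The defaults are source `{1,2,3,4} / {5} / {6}` and
#' target `{1} / {2} / {3,4,5,6}`.
#'
#' @param cohort List of `semg_recording`s.
#' @param source_train_trials,source_val_trials,source_test_trials Trial ids
#'   for the source-domain partitions.
#' @param target_calib_trials,target_val_trials,target_test_trials Trial ids
#'   for the target-domain partitions.
#' @return A list of `semg_split_plan`, one per subject (the fold target).
#' @export
make_loso_folds <- function(cohort,
                            source_train_trials = 1:4,
                            source_val_trials = 5L,
                            source_test_trials = 6L,
                            target_calib_trials = 1L,
                            target_val_trials = 2L,
                            target_test_trials = 3:6) {
  subjects <- sort(unique(vapply(cohort, `[[`, character(1), "subject_id")))
  if (length(subjects) < 2L) stop("LOSO needs at least 2 subjects", call. = FALSE)
  needed <- sort(unique(c(source_train_trials, source_val_trials, source_test_trials,
                          target_calib_trials, target_val_trials, target_test_trials)))
  # check every (subject, gesture) has the required trials
  key <- data.frame(
    subject = vapply(cohort, `[[`, character(1), "subject_id"),
    gesture = vapply(cohort, `[[`, character(1), "gesture_id"),
    trial = vapply(cohort, `[[`, integer(1), "trial_id"),
    stringsAsFactors = FALSE
  )
  for (s in subjects) {
    for (g in unique(key$gesture[key$subject == s])) {
      have <- key$trial[key$subject == s & key$gesture == g]
      miss <- setdiff(needed, have)
      if (length(miss) > 0L) {
        stop(sprintf("subject %s gesture %s is missing trial(s) %s required by the split plan",
                     s, g, paste(miss, collapse = ",")), call. = FALSE)
      }
    }
  }
  lapply(subjects, function(target) {
    plan <- structure(
      list(
        target_subject = target,
        source_subjects = setdiff(subjects, target),
        source_train_trials = as.integer(source_train_trials),
        source_val_trials = as.integer(source_val_trials),
        source_test_trials = as.integer(source_test_trials),
        target_calib_trials = as.integer(target_calib_trials),
        target_val_trials = as.integer(target_val_trials),
        target_test_trials = as.integer(target_test_trials)
      ),
      class = "semg_split_plan"
    )
    assert_split_plan(plan)
    plan
  })
}

#' Validate the leakage guards of a split plan
#'
#' Checks that the target subject is excluded from the source domain and that
#' trial lists within each domain are pairwise disjoint, so no (subject,
#' trial) pair can appear in both a training/scaler-fit partition and a test
#' partition.
#'
#' @param plan A `semg_split_plan`.
#' @return Invisibly `TRUE`; stops with an informative error on violation.
#' @export
assert_split_plan <- function(plan) {
  stopifnot(inherits(plan, "semg_split_plan"))
  if (plan$target_subject %in% plan$source_subjects) {
    stop("leakage: target subject appears among source subjects", call. = FALSE)
  }
  src <- list(train = plan$source_train_trials, val = plan$source_val_trials,
              test = plan$source_test_trials)
  tgt <- list(calib = plan$target_calib_trials, val = plan$target_val_trials,
              test = plan$target_test_trials)
  for (side in list(src, tgt)) {
    all_t <- unlist(side)
    if (anyDuplicated(all_t)) {
      stop("leakage: a trial id is assigned to more than one partition", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Select the recordings of one partition of a fold.
select_recordings <- function(cohort, subjects, trials) {
  keep <- vapply(cohort, function(r) {
    r$subject_id %in% subjects && r$trial_id %in% trials
  }, logical(1))
  cohort[keep]
}

#' Extract the six partitions of a fold as segment batches
#'
#' Segments every partition of `plan` with the shared window geometry. No
#' standardization is applied here; fit the scaler on `$source_train` and
#' apply it to the rest.
#'
#' @param cohort List of `semg_recording`s.
#' @param plan A `semg_split_plan`.
#' @inheritParams segment_recording
#' @return Named list of `semg_segments`: `source_train`, `source_val`,
#'   `source_test`, `target_calib`, `target_val`, `target_test`.
#' @export
fold_segments <- function(cohort, plan, window_ms = 250, stride_ms = 125) {
  assert_split_plan(plan)
  parts <- list(
    source_train = select_recordings(cohort, plan$source_subjects, plan$source_train_trials),
    source_val   = select_recordings(cohort, plan$source_subjects, plan$source_val_trials),
    source_test  = select_recordings(cohort, plan$source_subjects, plan$source_test_trials),
    target_calib = select_recordings(cohort, plan$target_subject, plan$target_calib_trials),
    target_val   = select_recordings(cohort, plan$target_subject, plan$target_val_trials),
    target_test  = select_recordings(cohort, plan$target_subject, plan$target_test_trials)
  )
  lapply(parts, segment_cohort, window_ms = window_ms, stride_ms = stride_ms)
}

#' One-hot encode labels against an ordered class list
#'
#' @param labels Character vector of gesture ids.
#' @param class_list Ordered character vector of all classes.
#' @return N x K 0/1 matrix; column order follows `class_list`.
#' @export
one_hot <- function(labels, class_list) {
  idx <- match(labels, class_list)
  if (anyNA(idx)) {
    stop(sprintf("label(s) outside the class list: %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  y <- matrix(0, nrow = length(labels), ncol = length(class_list))
  y[cbind(seq_along(labels), idx)] <- 1
  colnames(y) <- class_list
  y
}
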