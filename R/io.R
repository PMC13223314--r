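# Cohort, segment, and model persistence --------------------------------------
#
# All on-disk formats are plain text: one CSV per trial plus a manifest CSV
# for cohorts; CSV + JSON sidecar for segment batches; self-describing JSON
# for model checkpoints (architecture config, parameters, scaler, class
# list, schema version).

#' Write a cohort as per-trial CSVs plus a manifest
#'
#' Each recording becomes `<subject>_<gesture>_t<trial>.csv` with one column
#' per channel (header `ch1..chC`); `manifest.csv` lists
#' `subject_id,gesture_id,trial_id,fs_hz,path`.
#'
#' @param cohort List of `semg_recording`s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(r) {
    fname <- sprintf("%s_%s_t%d.csv", r$subject_id, r$gesture_id, r$trial_id)
    m <- data.table::as.data.table(r$samples)
    data.table::setnames(m, paste0("ch", seq_len(ncol(r$samples))))
    data.table::fwrite(m, file.path(dir, fname))
    data.frame(subject_id = r$subject_id, gesture_id = r$gesture_id,
               trial_id = r$trial_id, fs_hz = r$fs, path = fname,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort from a manifest directory
#'
#' Tolerates per-trial differences in recording length; requires a shared
#' channel count and sampling rate across the cohort.
#'
#' @param dir Directory containing `manifest.csv` (layout of
#'   [write_cohort()]).
#' @return List of `semg_recording`s.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- data.table::fread(mpath)
  needed <- c("subject_id", "gesture_id", "trial_id", "fs_hz", "path")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- data.table::fread(file.path(dir, manifest$path[i]))
    new_recording(manifest$subject_id[i], manifest$gesture_id[i],
                  manifest$trial_id[i], as.matrix(m), manifest$fs_hz[i])
  })
  c_ch <- unique(vapply(cohort, function(r) ncol(r$samples), integer(1)))
  fs <- unique(vapply(cohort, `[[`, numeric(1), "fs"))
  if (length(c_ch) != 1L || length(fs) != 1L) {
    stop("cohort mixes channel counts or sampling rates", call. = FALSE)
  }
  cohort
}

#' Persist a segment batch as CSV + JSON sidecar
#'
#' `segments.csv` holds one row per segment (T*C values, time-major within
#' channel); `meta.json` records shapes, labels, provenance, and window
#' geometry.
#'
#' @param batch A `semg_segments`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_segments <- function(batch, dir) {
  stopifnot(inherits(batch, "semg_segments"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(batch$segments)
  flat <- batch$segments
  dim(flat) <- c(d[1L], d[2L] * d[3L])
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "segments.csv"), col.names = FALSE)
  meta <- list(
    n = d[1L], n_samples = d[2L], n_channels = d[3L],
    labels = batch$labels, subject_ids = batch$subject_ids,
    trial_ids = batch$trial_ids, window_ms = batch$window_ms,
    stride_ms = batch$stride_ms, fs = batch$fs, schema = "semg_segments/1"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a segment batch written by [write_segments()]
#' @param dir Directory with `segments.csv` and `meta.json`.
#' @return A `semg_segments`.
#' @export
read_segments <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(file.path(dir, "segments.csv"),
                                      header = FALSE))
  segs <- array(as.numeric(flat),
                dim = c(meta$n, meta$n_samples, meta$n_channels))
  new_segment_batch(segs, meta$labels, meta$subject_ids, meta$trial_ids,
                    meta$window_ms, meta$stride_ms, meta$fs)
}

param_list_to_json <- function(params) {
  lapply(params, function(p) list(dim = dim(p) %||% length(p), data = as.numeric(p)))
}

param_list_from_json <- function(x) {
  lapply(x, function(p) {
    v <- as.numeric(p$data)
    d <- as.integer(unlist(p$dim))
    if (length(d) > 1L) dim(v) <- d
    v
  })
}

#' Save a model checkpoint as self-describing JSON
#'
#' Supports `semg_csae` and `semg_classifier`. The checkpoint contains a
#' schema version, the architecture configuration, all parameters, the class
#' list (classifier), and optionally the standardization scaler used with
#' the model.
#'
#' @param model The model object.
#' @param path Output `.json` path.
#' @param scaler Optional `semg_scaler` stored alongside.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, scaler = NULL) {
  obj <- if (inherits(model, "semg_csae")) {
    list(schema = "semg_csae/1", config = unclass(model$config),
         input_shape = model$input_shape,
         params = param_list_to_json(model$params))
  } else if (inherits(model, "semg_classifier")) {
    list(schema = "semg_classifier/1", config = unclass(model$config),
         input_shape = model$input_shape, class_list = model$class_list,
         enc_layers = lapply(model$enc_layers, unclass),
         enc_params = param_list_to_json(model$enc_params),
         head_params = param_list_to_json(model$head_params))
  } else stop("unsupported model class", call. = FALSE)
  if (!is.null(scaler)) obj$scaler <- unclass(scaler)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return The model; any stored scaler is attached as attribute `"scaler"`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  out <- if (identical(obj$schema, "semg_csae/1")) {
    cfg <- do.call(csae_config, obj$config)
    m <- build_csae(cfg, unlist(obj$input_shape))
    m$params <- param_list_from_json(obj$params)[names(m$params)]
    m
  } else if (identical(obj$schema, "semg_classifier/1")) {
    cfg <- do.call(classifier_config, obj$config)
    enc_layers <- lapply(obj$enc_layers, function(ly) do.call(nn_layer, ly))
    m <- structure(
      list(enc_layers = enc_layers,
           enc_params = param_list_from_json(obj$enc_params),
           head_layers = head_layer_graph(
             enc_layers[[5L]]$out_ch, cfg, cfg$n_classes),
           head_params = param_list_from_json(obj$head_params),
           config = cfg, class_list = unlist(obj$class_list),
           input_shape = unlist(obj$input_shape), history = NULL),
      class = "semg_classifier"
    )
    m
  } else stop("unknown checkpoint schema: ", obj$schema, call. = FALSE)
  if (!is.null(obj$scaler)) {
    attr(out, "scaler") <- structure(
      list(mean = unlist(obj$scaler$mean), sd = unlist(obj$scaler$sd),
           fitted_on = obj$scaler$fitted_on),
      class = "semg_scaler")
  }
  out
}
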