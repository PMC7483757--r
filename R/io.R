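#' Write trials as a BIDS-style events table
#'
#' Columns: onset, duration, trial_type, rating, block (tab-separated,
#' `n/a` for missing, onsets within-block seconds).
#'
#' @param design A [make_task_design()] object (or a [design_events()] data
#'   frame).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  ev <- if (inherits(design, "task_design")) design_events(design) else design
  out <- ev[, intersect(c("onset", "duration", "trial_type", "rating",
                          "block"), names(ev))]
  out[] <- lapply(out, function(x) ifelse(is.na(x), "n/a", as.character(x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' @param path File written by [write_events_tsv()] (or any events.tsv with
#'   onset/duration/trial_type columns; `n/a` becomes `NA`).
#' @return Data frame with numeric onset/duration and character trial_type.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  for (col in intersect(c("onset", "duration", "rating", "block"), names(ev)))
    ev[[col]] <- as.numeric(ev[[col]])
  ev
}

#' Write a voxel time series as TSV with a JSON sidecar
#'
#' The signal is written as a voxels x volumes tab-separated matrix; the
#' sampling interval, block membership and decodable flags go to a
#' `<path>.json` sidecar.
#'
#' @param ts A [voxel_timeseries()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_voxels_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tr_seconds = ts$tr_seconds,
                            block_id = ts$block_id,
                            decodable = ts$decodable),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel time series written by [write_voxels_tsv()]
#'
#' @param path TSV path (the `<path>.json` sidecar must exist).
#' @return A [voxel_timeseries()].
#' @export
read_voxels_tsv <- function(path) {
  dat <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(dat) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  voxel_timeseries(dat, side$tr_seconds, side$block_id, side$decodable)
}

#' Write a run as a 4D NIfTI volume
#'
#' Voxels are laid out along the first axis of a `n_voxels x 1 x 1 x volumes`
#' array (synthetic data has no spatial structure); real data should keep its
#' own grid. The TR is recorded in the 4th pixdim.
#'
#' @param ts A [voxel_timeseries()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_nifti_run <- function(ts, path) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  arr <- array(ts$data, dim = c(nrow(ts$data), 1L, 1L, ncol(ts$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, ts$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI run as a voxel time series
#'
#' @param path A 4D NIfTI file.
#' @param block_id,decodable Optional per-volume metadata (defaults: one
#'   block, all decodable).
#' @return A [voxel_timeseries()] with voxels flattened in array order.
#' @export
read_nifti_run <- function(path, block_id = NULL, decodable = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop_shape("expected a 4D NIfTI volume")
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  voxel_timeseries(matrix(img, prod(d[1:3]), d[4]), tr, block_id, decodable)
}

#' Serialize a trained classifier to JSON
#'
#' @param model An `ia_classifier`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "ia_classifier"))
  jsonlite::write_json(
    list(weights = model$weights, intercepts = as.list(model$intercepts),
         penalty = model$penalty, condition_order = model$condition_order,
         training_volume_count = model$training_volume_count,
         standardize = isTRUE(model$standardize),
         center = model$center, scale_sd = model$scale_sd),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier written by [write_classifier_json()]
#'
#' @param path JSON path.
#' @return An `ia_classifier`.
#' @export
read_classifier_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.matrix(x$weights)
  rownames(w) <- x$condition_order
  structure(list(weights = w,
                 intercepts = stats::setNames(unlist(x$intercepts),
                                              x$condition_order),
                 penalty = x$penalty, condition_order = x$condition_order,
                 training_volume_count = x$training_volume_count,
                 standardize = isTRUE(x$standardize),
                 center = x$center, scale_sd = x$scale_sd),
            class = "ia_classifier")
}

#' Write decoded meditation output as TSV
#'
#' One row per decodable volume: volume index, block, the three evidence
#' values, raw and smoothed decisions.
#'
#' @param run A `decoded_run`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_decoded_tsv <- function(run, path) {
  stopifnot(inherits(run, "decoded_run"))
  ev <- as.data.frame(run$evidence)
  names(ev) <- paste0("evidence_", tolower(names(ev)))
  out <- cbind(data.frame(volume = seq_len(run$n_volumes),
                          block = run$block_id),
               ev,
               data.frame(raw_decision = run$raw_decisions,
                          smoothed_decision = run$smoothed_decisions))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mental events as a BIDS-style events table
#'
#' @param run A `decoded_run` (or its `events` data frame).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_event_tsv <- function(run, path) {
  ev <- if (inherits(run, "decoded_run")) run$events else run
  out <- data.frame(onset = ev$onset_seconds, duration = ev$duration_seconds,
                    trial_type = ev$state, block = ev$block)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-subject attention metrics as a long TSV
#'
#' @param metrics_list List of [compute_metrics()] results (one per subject,
#'   names used as subject ids when present).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_metrics_tsv <- function(metrics_list, path) {
  ids <- names(metrics_list)
  if (is.null(ids)) ids <- as.character(seq_along(metrics_list))
  long <- do.call(rbind, lapply(seq_along(metrics_list), function(i) {
    st <- metrics_list[[i]]$states
    cbind(subject = ids[i], st,
          pct_excluded = metrics_list[[i]]$pct_excluded)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
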