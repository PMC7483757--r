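#' Construct a voxel-by-time series
#'
#' The basic data unit every pipeline stage consumes: a numeric voxels x
#' volumes matrix with its sampling interval and per-volume block membership.
#'
#' @param data Numeric matrix, voxels in rows, volumes in columns.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param block_id Integer vector, one entry per volume (default: all 1).
#' @param decodable Optional logical vector flagging volumes that enter
#'   decoding (instruction periods are flagged `FALSE`); default all `TRUE`.
#' @return An object of class `voxel_timeseries`.
#' @export
voxel_timeseries <- function(data, tr_seconds, block_id = NULL,
                             decodable = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop_invalid("data must be a finite numeric matrix")
  if (tr_seconds <= 0) stop_invalid("tr_seconds must be positive")
  if (is.null(block_id)) block_id <- rep(1L, ncol(data))
  if (length(block_id) != ncol(data))
    stop_shape("block_id length must equal the number of volumes")
  if (is.null(decodable)) decodable <- rep(TRUE, ncol(data))
  if (length(decodable) != ncol(data))
    stop_shape("decodable length must equal the number of volumes")
  structure(list(data = data, tr_seconds = tr_seconds,
                 block_id = as.integer(block_id),
                 decodable = as.logical(decodable)),
            class = "voxel_timeseries")
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("<voxel_timeseries> %d voxels x %d volumes, TR = %g s, %d block(s)\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              length(unique(x$block_id))))
  invisible(x)
}

#' Construct a per-volume label series
#'
#' @param labels Character vector of condition identifiers, `NA` for
#'   unlabelled volumes (baseline, instructions).
#' @param block_id Integer vector of block membership per volume.
#' @param tr_seconds Sampling interval (s).
#' @param trial_id Optional integer vector mapping labelled volumes to the
#'   design-wide trial index (used for trial-level accuracy).
#' @param lag_seconds Hemodynamic shift already applied to the labels (s).
#' @return An object of class `label_series`.
#' @export
label_series <- function(labels, block_id, tr_seconds, trial_id = NULL,
                         lag_seconds = 0) {
  if (length(block_id) != length(labels))
    stop_shape("block_id length must equal labels length")
  if (lag_seconds < 0) stop_invalid("lag_seconds must be non-negative")
  if (is.null(trial_id)) trial_id <- rep(NA_integer_, length(labels))
  structure(list(labels = as.character(labels),
                 block_id = as.integer(block_id),
                 trial_id = as.integer(trial_id),
                 tr_seconds = tr_seconds, lag_seconds = lag_seconds),
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series> %d volumes (%d labelled), lag = %g s\n",
              length(x$labels), sum(!is.na(x$labels)), x$lag_seconds))
  invisible(x)
}

#' Per-volume condition labels implied by a task design
#'
#' Expands a task design into one unshifted label series per block: trial
#' volumes carry the trial's condition, baseline and 2 s instruction volumes
#' are unlabelled. Apply [shift_labels()] before training to account for
#' hemodynamic lag.
#'
#' @param design A [make_task_design()] object.
#' @return List of [label_series()] objects, one per block.
#' @export
labels_from_design <- function(design) {
  stopifnot(inherits(design, "task_design"))
  tr <- design$tr_seconds
  trial0 <- 0L
  lapply(seq_along(design$blocks), function(b) {
    blk <- design$blocks[[b]]
    n_vol <- as.integer(round(blk$duration_seconds / tr))
    lab <- rep(NA_character_, n_vol)
    tid <- rep(NA_integer_, n_vol)
    for (i in seq_len(nrow(blk$trials))) {
      v0 <- as.integer(round(blk$trials$onset_seconds[i] / tr))
      nv <- as.integer(round(blk$trials$duration_seconds[i] / tr))
      lab[(v0 + 1L):(v0 + nv)] <- blk$trials$condition[i]
      tid[(v0 + 1L):(v0 + nv)] <- trial0 + i
    }
    trial0 <<- trial0 + nrow(blk$trials)
    label_series(lab, rep(b, n_vol), tr, trial_id = tid)
  })
}

#' Concatenate per-block series into one run
#'
#' @param blocks List of [voxel_timeseries()] objects sharing a voxel grid.
#' @param labels Optional matching list of [label_series()] objects.
#' @return A single `voxel_timeseries` (and, if `labels` is given, a list
#'   with elements `ts` and `labels`).
#' @export
concat_blocks <- function(blocks, labels = NULL) {
  nv <- vapply(blocks, function(b) nrow(b$data), integer(1))
  if (length(unique(nv)) != 1L) stop_shape("blocks differ in voxel count")
  ts <- voxel_timeseries(do.call(cbind, lapply(blocks, `[[`, "data")),
                         blocks[[1]]$tr_seconds,
                         unlist(lapply(blocks, `[[`, "block_id")),
                         unlist(lapply(blocks, `[[`, "decodable")))
  if (is.null(labels)) return(ts)
  lab <- label_series(unlist(lapply(labels, `[[`, "labels")),
                      unlist(lapply(labels, `[[`, "block_id")),
                      labels[[1]]$tr_seconds,
                      unlist(lapply(labels, `[[`, "trial_id")),
                      labels[[1]]$lag_seconds)
  list(ts = ts, labels = lab)
}
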