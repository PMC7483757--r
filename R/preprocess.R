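#' Remove per-voxel linear trends
#'
#' Fits and subtracts a per-voxel least-squares line (intercept + slope over
#' volume index) independently within each block, mirroring native-space
#' linear detrending of separate scanner runs. The output has mean ~0 per
#' voxel per block and is invariant to any added linear trend.
#'
#' @param ts A [voxel_timeseries()].
#' @return A detrended `voxel_timeseries` of the same shape.
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  out <- ts$data
  for (b in unique(ts$block_id)) {
    idx <- which(ts$block_id == b)
    if (length(idx) < 3L)
      stop_invalid("detrend_linear needs at least 3 volumes per block")
    X <- cbind(1, seq_along(idx))
    P <- X %*% solve(crossprod(X), t(X))
    out[, idx] <- ts$data[, idx, drop = FALSE] -
      ts$data[, idx, drop = FALSE] %*% P
  }
  ts$data <- out
  ts
}

#' Regress confound time courses out of every voxel
#'
#' Per voxel, returns the residual of a least-squares projection onto the
#' confound columns plus an intercept (e.g. motion parameters). Rank-deficient
#' confound matrices trigger a warning and a projection onto the column span
#' (the pseudo-inverse solution).
#'
#' @param ts A [voxel_timeseries()].
#' @param confounds Numeric matrix, volumes x k (k >= 1).
#' @return A `voxel_timeseries` of residuals.
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(ts$data))
    stop_shape("confound rows must equal the volume count")
  if (ncol(confounds) < 1L) stop_invalid("need at least one confound column")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("confound matrix is rank deficient; projecting onto its column span")
  ts$data <- t(qr.resid(qrX, t(ts$data)))
  ts
}

#' Shift condition labels for hemodynamic lag
#'
#' Moves every label later in time by `lag_seconds`, within block only: the
#' label originally at time t applies to the volume at t + lag. Volumes at the
#' start of a block left without a shifted label become unlabelled, and labels
#' pushed past the block end are dropped. Neural events reach the BOLD signal
#' with a delay of roughly 6 s, the default.
#'
#' @param labels A [label_series()].
#' @param lag_seconds Non-negative shift (default 6 s). If not divisible by
#'   the TR it is rounded to the nearest whole volume with a warning.
#' @param tr_seconds Sampling interval; defaults to the series' own.
#' @return A shifted `label_series` with `lag_seconds` recorded.
#' @export
shift_labels <- function(labels, lag_seconds = 6, tr_seconds = NULL) {
  stopifnot(inherits(labels, "label_series"))
  if (lag_seconds < 0) stop_invalid("lag_seconds must be non-negative")
  if (is.null(tr_seconds)) tr_seconds <- labels$tr_seconds
  k <- lag_seconds / tr_seconds
  if (abs(k - round(k)) > 1e-8) {
    warning(sprintf("lag %g s is not a multiple of TR %g s; rounding to %d volume(s)",
                    lag_seconds, tr_seconds, as.integer(round(k))))
  }
  k <- as.integer(round(k))
  lab <- rep(NA_character_, length(labels$labels))
  tid <- rep(NA_integer_, length(labels$labels))
  for (b in unique(labels$block_id)) {
    idx <- which(labels$block_id == b)
    n <- length(idx)
    if (k < n) {
      src <- idx[seq_len(n - k)]
      dst <- idx[seq_len(n - k) + k]
      lab[dst] <- labels$labels[src]
      tid[dst] <- labels$trial_id[src]
    }
  }
  label_series(lab, labels$block_id, labels$tr_seconds, trial_id = tid,
               lag_seconds = labels$lag_seconds + k * tr_seconds)
}
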