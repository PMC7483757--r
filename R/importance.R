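#' Voxelwise classifier importance for one condition
#'
#' Importance = classifier weight x average z-scored activation during the
#' condition: each voxel's time course is z-scored across the supplied
#' volumes, averaged over the condition's labelled volumes, and multiplied by
#' that voxel's weight in the condition's binary model. Voxels where weight
#' and z-scored activation are both positive are classed `positive`, both
#' negative `negative`; mixed signs (which do not aid the classification in a
#' consistent direction) are classed `none`.
#'
#' @param model An `ia_classifier`.
#' @param data A [voxel_timeseries()] on the model's voxel grid (typically
#'   motion-regressed task data; see [regress_confounds()]).
#' @param labels A [label_series()] aligned with `data` (shifted).
#' @param condition Condition to map.
#' @param z_axis `"time"` (default: z-score each voxel across volumes before
#'   averaging) or `"voxels"` (z-score the raw condition means across
#'   voxels).
#' @return Object of class `importance_map`: data frame with `voxel`,
#'   `weight`, `activation` (z-scored mean), `importance`, `class`; plus the
#'   condition and subject grid size as attributes.
#' @export
compute_importance <- function(model, data, labels, condition,
                               z_axis = c("time", "voxels")) {
  stopifnot(inherits(model, "ia_classifier"))
  z_axis <- match.arg(z_axis)
  if (!condition %in% model$condition_order)
    stop_missing_class(sprintf("condition %s not in model", condition))
  X <- if (inherits(data, "voxel_timeseries")) data$data else as.matrix(data)
  lab <- if (inherits(labels, "label_series")) labels$labels else labels
  if (length(lab) != ncol(X))
    stop_shape("labels length must equal the volume count")
  idx <- which(!is.na(lab) & lab == condition)
  if (!length(idx))
    stop_missing_class(sprintf("no labelled volumes for condition %s",
                               condition))
  if (z_axis == "time") {
    mu <- rowMeans(X)
    sdv <- apply(X, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    act <- (rowMeans(X[, idx, drop = FALSE]) - mu) / sdv
  } else {
    m <- rowMeans(X[, idx, drop = FALSE])
    act <- as.numeric(scale(m))
  }
  w <- model$weights[condition, ]
  imp <- w * act
  cls <- ifelse(w > 0 & act > 0, "positive",
                ifelse(w < 0 & act < 0, "negative", "none"))
  structure(data.frame(voxel = seq_along(w), weight = unname(w),
                       activation = act, importance = imp, class = cls),
            condition = condition, class = c("importance_map", "data.frame"))
}

#' Threshold an importance map at +/- k SD
#'
#' Importance values are z-scored across voxels; voxels with |z| at or above
#' the threshold *and* a concordant sign class are retained as the
#' condition's most important voxels.
#'
#' @param map An [compute_importance()] result.
#' @param sd_threshold Threshold in SD units (default 2).
#' @return The map with added columns `z` and `retained`.
#' @export
threshold_map <- function(map, sd_threshold = 2) {
  stopifnot(inherits(map, "importance_map"))
  s <- stats::sd(map$importance)
  if (nrow(map) < 2L || !is.finite(s) || s == 0) {
    warning("importance values have zero variance; nothing retained")
    map$z <- 0
    map$retained <- FALSE
    return(map)
  }
  map$z <- (map$importance - mean(map$importance)) / s
  map$retained <- abs(map$z) >= sd_threshold & map$class != "none"
  map
}

#' Across-subject frequency of important voxels
#'
#' Counts, per voxel, in how many subjects the voxel survived importance
#' thresholding for the condition (positive and negative importances pooled
#' by default).
#'
#' @param maps List of thresholded [threshold_map()] results on one grid.
#' @param sign `"both"` (default), `"positive"` or `"negative"`.
#' @return Integer vector, one count per voxel (0..length(maps)).
#' @export
frequency_map <- function(maps, sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  if (!length(maps)) return(integer(0))
  nv <- vapply(maps, nrow, integer(1))
  if (length(unique(nv)) != 1L)
    stop_shape("importance maps are on different voxel grids")
  counts <- integer(nv[1])
  for (m in maps) {
    keep <- m$retained
    if (sign != "both") keep <- keep & m$class == sign
    counts <- counts + as.integer(keep)
  }
  counts
}

#' Fraction of retained importance voxels inside a mask
#'
#' @param map A thresholded [threshold_map()] result.
#' @param mask Logical vector on the same voxel grid (e.g. a cortical or
#'   subcortical atlas mask supplied by the user).
#' @return Percentage of retained voxels falling inside the mask, or `NA` if
#'   no voxel is retained.
#' @export
mask_fraction <- function(map, mask) {
  stopifnot(inherits(map, "importance_map"))
  if (length(mask) != nrow(map))
    stop_shape("mask length must equal the voxel count")
  n_ret <- sum(map$retained)
  if (n_ret == 0) return(NA_real_)
  100 * sum(map$retained & mask) / n_ret
}
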