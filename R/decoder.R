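#' Decode a meditation run into three mental states
#'
#' Applies a classifier trained on all five task conditions to every
#' decodable volume of an independent run, restricted to the three
#' meditation-relevant states (Breath, MW, Self): the three binary evidence
#' values are computed (not renormalized) and the argmax is the raw decision,
#' so Feet/Sounds are never emitted.
#'
#' @param model An `ia_classifier` trained on all five conditions.
#' @param run A [voxel_timeseries()]; volumes with `decodable = FALSE`
#'   (instruction periods) are skipped.
#' @param allowed States to decode among (default [meditation_states()]).
#' @return List with `evidence` (decodable volumes x states), `decisions`
#'   (raw argmax decisions), `block_id` and `tr_seconds` for the decodable
#'   volumes.
#' @export
decode_run <- function(model, run, allowed = meditation_states()) {
  stopifnot(inherits(model, "ia_classifier"),
            inherits(run, "voxel_timeseries"))
  keep <- which(run$decodable)
  score <- predict_evidence(model, run$data[, keep, drop = FALSE],
                            type = "link")
  ev <- stats::plogis(pmin(pmax(score, -30), 30))
  list(evidence = ev[, allowed, drop = FALSE],
       decisions = decide(score, allowed = allowed),
       block_id = run$block_id[keep], tr_seconds = run$tr_seconds)
}

#' Relabel singleton decisions between two same-state events
#'
#' A single incongruous decision sandwiched between two runs of one common
#' state (e.g. MW MW MW Self MW MW -> all MW) is relabelled to the flanking
#' state. "Event-like" flanks are runs of at least `min_flank` volumes; run
#' structure is taken from the input in a single left-to-right pass, and
#' newly merged runs are not re-scanned unless `iterative = TRUE`. Runs never
#' merge across a block boundary.
#'
#' @param decisions Character vector of per-volume state decisions.
#' @param min_flank Minimum flanking run length (default 2).
#' @param block_id Optional block membership; smoothing respects boundaries.
#' @param iterative Re-scan until no singleton qualifies (default FALSE).
#' @return List with `decisions` (smoothed), `pct_smoothed` (percent of
#'   volumes relabelled) and `n_smoothed`.
#' @export
smooth_decisions <- function(decisions, min_flank = 2L, block_id = NULL,
                             iterative = FALSE) {
  if (!length(decisions)) stop_invalid("decisions must be non-empty")
  if (is.null(block_id)) block_id <- rep(1L, length(decisions))
  out <- decisions
  total_changed <- 0L
  repeat {
    changed <- 0L
    for (b in unique(block_id)) {
      idx <- which(block_id == b)
      r <- rle(out[idx])
      if (length(r$lengths) < 3L) next
      ends <- cumsum(r$lengths)
      for (j in 2:(length(r$lengths) - 1L)) {
        if (r$lengths[j] == 1L &&
            r$values[j - 1L] == r$values[j + 1L] &&
            r$lengths[j - 1L] >= min_flank &&
            r$lengths[j + 1L] >= min_flank) {
          out[idx[ends[j]]] <- r$values[j - 1L]
          changed <- changed + 1L
        }
      }
    }
    total_changed <- total_changed + changed
    if (!iterative || changed == 0L) break
  }
  list(decisions = out,
       pct_smoothed = 100 * total_changed / length(decisions),
       n_smoothed = total_changed)
}

#' Extract mental events from smoothed decisions
#'
#' A mental event is a maximal run of at least `min_event_length` consecutive
#' identical state decisions; shorter runs are excluded and counted. Events
#' never span a block boundary (a scan gap separates the two meditation
#' blocks).
#'
#' @param decisions Character vector of (smoothed) per-volume decisions.
#' @param min_event_length Minimum run length in volumes (default 3).
#' @param tr_seconds Sampling interval (default 1 s).
#' @param block_id Optional block membership per volume.
#' @return List with `events` (data frame: state, onset_seconds,
#'   duration_seconds, n_volumes, block; onsets 0-based over the decodable
#'   volumes) and `pct_excluded` (percent of volumes in sub-threshold runs).
#' @export
extract_events <- function(decisions, min_event_length = 3L, tr_seconds = 1,
                           block_id = NULL) {
  if (!length(decisions)) stop_invalid("decisions must be non-empty")
  if (is.null(block_id)) block_id <- rep(1L, length(decisions))
  rows <- list()
  excluded <- 0L
  for (b in unique(block_id)) {
    idx <- which(block_id == b)
    r <- rle(decisions[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (r$lengths[j] >= min_event_length) {
        rows[[length(rows) + 1L]] <- data.frame(
          state = r$values[j],
          onset_seconds = (idx[starts[j]] - 1L) * tr_seconds,
          duration_seconds = r$lengths[j] * tr_seconds,
          n_volumes = r$lengths[j], block = b)
      } else {
        excluded <- excluded + r$lengths[j]
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, rows)
            else data.frame(state = character(0), onset_seconds = numeric(0),
                            duration_seconds = numeric(0),
                            n_volumes = integer(0), block = integer(0))
  list(events = events, pct_excluded = 100 * excluded / length(decisions))
}

#' Full meditation decoding: evidence, smoothing, events
#'
#' Convenience wrapper chaining [decode_run()], [smooth_decisions()] and
#' [extract_events()] into a `decoded_run`.
#'
#' @inheritParams decode_run
#' @param smooth Apply singleton smoothing (default TRUE).
#' @param min_flank Passed to [smooth_decisions()].
#' @param min_event_length Passed to [extract_events()].
#' @return Object of class `decoded_run`: `evidence`, `raw_decisions`,
#'   `smoothed_decisions`, `events`, `pct_smoothed`, `pct_excluded`,
#'   `block_id`, `n_volumes`, `tr_seconds`.
#' @export
decode_meditation <- function(model, run, allowed = meditation_states(),
                              smooth = TRUE, min_flank = 2L,
                              min_event_length = 3L) {
  dec <- decode_run(model, run, allowed)
  sm <- if (smooth) {
    smooth_decisions(dec$decisions, min_flank = min_flank,
                     block_id = dec$block_id)
  } else {
    list(decisions = dec$decisions, pct_smoothed = 0, n_smoothed = 0L)
  }
  ee <- extract_events(sm$decisions, min_event_length = min_event_length,
                       tr_seconds = dec$tr_seconds, block_id = dec$block_id)
  structure(list(evidence = dec$evidence, raw_decisions = dec$decisions,
                 smoothed_decisions = sm$decisions, events = ee$events,
                 pct_smoothed = sm$pct_smoothed,
                 pct_excluded = ee$pct_excluded,
                 block_id = dec$block_id,
                 n_volumes = length(dec$decisions),
                 tr_seconds = dec$tr_seconds,
                 states = allowed),
            class = "decoded_run")
}

#' @export
print.decoded_run <- function(x, ...) {
  cat(sprintf("<decoded_run> %d volumes, %d events; %.1f%% smoothed, %.1f%% excluded\n",
              x$n_volumes, nrow(x$events), x$pct_smoothed, x$pct_excluded))
  invisible(x)
}
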