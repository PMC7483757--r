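# Independent brute-force references the fast implementations are checked
# against. These deliberately use naive position-by-position scans, not rle().

# Singleton smoothing: position i is relabelled iff it differs from both
# neighbours, the neighbours share a value, and the maximal same-value
# stretches touching i on each side are both >= min_flank. Decisions are
# taken on the ORIGINAL sequence (single pass), per block.
oracle_smooth <- function(x, min_flank = 2L, block_id = NULL) {
  if (is.null(block_id)) block_id <- rep(1L, length(x))
  out <- x
  for (i in seq_along(x)) {
    if (i == 1L || i == length(x)) next
    if (block_id[i - 1L] != block_id[i] || block_id[i + 1L] != block_id[i])
      next
    if (x[i] == x[i - 1L] || x[i] == x[i + 1L]) next
    if (x[i - 1L] != x[i + 1L]) next
    left <- 0L; j <- i - 1L
    while (j >= 1L && block_id[j] == block_id[i] && x[j] == x[i - 1L]) {
      left <- left + 1L; j <- j - 1L
    }
    right <- 0L; j <- i + 1L
    while (j <= length(x) && block_id[j] == block_id[i] && x[j] == x[i + 1L]) {
      right <- right + 1L; j <- j + 1L
    }
    if (left >= min_flank && right >= min_flank) out[i] <- x[i - 1L]
  }
  list(decisions = out, n_smoothed = sum(out != x))
}

# Event extraction: walk the sequence, cutting runs at value changes and
# block boundaries; keep runs >= min_len.
oracle_events <- function(x, min_len = 3L, block_id = NULL) {
  if (is.null(block_id)) block_id <- rep(1L, length(x))
  events <- list(); excluded <- 0L
  start <- 1L
  for (i in seq_along(x)) {
    end_of_run <- i == length(x) || x[i + 1L] != x[i] ||
      block_id[i + 1L] != block_id[i]
    if (end_of_run) {
      len <- i - start + 1L
      if (len >= min_len) {
        events[[length(events) + 1L]] <-
          data.frame(state = x[start], onset = start - 1L, n_volumes = len)
      } else {
        excluded <- excluded + len
      }
      start <- i + 1L
    }
  }
  list(events = if (length(events)) do.call(rbind, events)
                else data.frame(state = character(0), onset = integer(0),
                                n_volumes = integer(0)),
       excluded = excluded)
}

# Label shifting by explicit reindexing: label at volume v (1-based) moves to
# volume v + k within its block; everything else is unlabelled.
oracle_shift <- function(labels, block_id, k) {
  out <- rep(NA_character_, length(labels))
  for (v in seq_along(labels)) {
    w <- v + k
    if (w <= length(labels) && block_id[w] == block_id[v])
      out[w] <- labels[v]
  }
  out
}

# Penalized logistic log-likelihood for direct maximization with optim().
pen_loglik <- function(theta, X, y, lambda) {
  eta <- drop(cbind(1, X) %*% theta)
  -sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta)))) +
    lambda * sum(theta[-1]^2)
}

# Shared small fixtures (built once per test run)
default_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- make_task_design(seed = 42)
    d
  }
})

small_subject <- local({
  s <- NULL
  function() {
    if (is.null(s))
      s <<- simulate_subject(default_design(), n_voxels = 60, snr = 2,
                             seed = 7)
    s
  }
})

small_cv <- local({
  cv <- NULL
  function() {
    if (is.null(cv)) cv <<- crossval_subject(small_subject())
    cv
  }
})

# a hand-built decoded_run for metric tests
fake_decoded_run <- function(decisions, block_id = NULL, tr = 1,
                             states = meditation_states()) {
  sm <- smooth_decisions(decisions, block_id = block_id)
  ee <- extract_events(sm$decisions, tr_seconds = tr, block_id = block_id)
  structure(list(evidence = NULL, raw_decisions = decisions,
                 smoothed_decisions = sm$decisions, events = ee$events,
                 pct_smoothed = sm$pct_smoothed,
                 pct_excluded = ee$pct_excluded,
                 block_id = if (is.null(block_id)) rep(1L, length(decisions))
                            else block_id,
                 n_volumes = length(decisions), tr_seconds = tr,
                 states = states),
            class = "decoded_run")
}

# metrics for a cohort of ground-truth dwell chains (no classifier), used by
# group-level power/calibration checks
chain_cohort_metrics <- function(n_subjects, occupancy, seed0) {
  lapply(seq_len(n_subjects), function(i) {
    truth <- withr::with_seed(seed0 + i, {
      iastates:::new_ground_truth(
        condition_patterns = matrix(0, 2, 5,
                                    dimnames = list(NULL, ia_conditions())),
        pattern_support = list(), snr = 0, occupancy = occupancy,
        hrf_lag_seconds = 6, trial_fidelity = numeric(0),
        noise = list(ar_phi = 0, drift_sd = 0))
    })
    med <- simulate_meditation(truth, n_volumes = 600, min_dwell = 3,
                               seed = seed0 + i)
    fake_decoded_run(med$states,
                     block_id = med$ts$block_id[med$ts$decodable])
  }) |> lapply(compute_metrics)
}
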