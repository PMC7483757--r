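#' Ground truth for a synthetic subject
#'
#' Internal constructor; created by [simulate_subject()]. Holds the planted
#' condition patterns (each loading on a known voxel subset), the
#' signal-to-noise ratio, the meditation-state occupancy targets, and the
#' noise settings, so downstream recovery can be scored exactly.
#'
#' @keywords internal
new_ground_truth <- function(condition_patterns, pattern_support, snr,
                             occupancy, hrf_lag_seconds, trial_fidelity,
                             noise) {
  if (abs(sum(occupancy) - 1) > 1e-8)
    stop_invalid("occupancy must sum to 1")
  if (snr < 0) stop_invalid("snr must be non-negative")
  structure(list(condition_patterns = condition_patterns,
                 pattern_support = pattern_support, snr = snr,
                 occupancy = occupancy, hrf_lag_seconds = hrf_lag_seconds,
                 trial_fidelity = trial_fidelity, noise = noise),
            class = "ground_truth")
}

#' Simulate one subject's internal-attention task fMRI data
#'
#' Emits per-block voxels x volumes matrices following the task design:
#' during each trial the condition's multivoxel pattern is added (delayed by
#' the hemodynamic lag), on top of a per-voxel linear drift and AR(1)
#' Gaussian noise with unit marginal variance. Each condition's pattern loads
#' on a random ~10% voxel subset with unit-RMS values, scaled by `snr`, so
#' `snr` is pattern amplitude over noise SD and `snr = 0` carries no
#' condition-dependent signal at all.
#'
#' Attention is not constant: every trial gets a latent fidelity multiplier
#' (log-normal, unit mean) that scales its pattern amplitude; the fidelities
#' are stored in the ground truth and drive [simulate_ratings()].
#'
#' @param design A [make_task_design()] object.
#' @param n_voxels Number of voxels (>= 2; default 500).
#' @param snr Pattern amplitude / noise SD (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param ar_phi AR(1) coefficient of the noise (default 0.3).
#' @param drift_sd SD across voxels of the per-block linear drift amplitude
#'   (signal units over the block; default 1).
#' @param pattern_density Fraction of voxels in each condition's support
#'   (default 0.1).
#' @param attention_sd SD of the log trial-fidelity multiplier (default 0.3;
#'   0 gives constant attention).
#' @param occupancy Named meditation occupancy targets over Breath/MW/Self
#'   used later by [simulate_meditation()] (default 0.5/0.25/0.25).
#' @return A list of class `ia_subject`: `blocks` (list of
#'   [voxel_timeseries()]), `labels` (list of unshifted [label_series()]),
#'   `truth` (ground truth), and `design`.
#' @export
simulate_subject <- function(design, n_voxels = 500L, snr = 1, seed,
                             ar_phi = 0.3, drift_sd = 1,
                             pattern_density = 0.1, attention_sd = 0.3,
                             occupancy = c(Breath = 0.5, MW = 0.25,
                                           Self = 0.25)) {
  stopifnot(inherits(design, "task_design"))
  if (n_voxels < 2L) stop_invalid("n_voxels must be at least 2")
  if (snr < 0) stop_invalid("snr must be non-negative")
  conditions <- design$conditions
  labels <- labels_from_design(design)
  lag <- 6

  withr::with_seed(as.integer(seed), {
    k <- max(2L, as.integer(round(pattern_density * n_voxels)))
    support <- lapply(conditions, function(cond) sort(sample.int(n_voxels, k)))
    names(support) <- conditions
    patterns <- matrix(0, n_voxels, length(conditions),
                       dimnames = list(NULL, conditions))
    for (cond in conditions) {
      v <- stats::rnorm(k)
      patterns[support[[cond]], cond] <- v / sqrt(mean(v^2))  # unit RMS
    }
    n_trials <- sum(vapply(design$blocks, function(b) nrow(b$trials),
                           integer(1)))
    fidelity <- exp(attention_sd * stats::rnorm(n_trials) - attention_sd^2 / 2)

    sig_labels <- lapply(labels, shift_labels, lag_seconds = lag)
    blocks <- vector("list", design$n_blocks)
    for (b in seq_len(design$n_blocks)) {
      n_vol <- length(labels[[b]]$labels)
      innov <- matrix(stats::rnorm(n_vol * n_voxels, sd = sqrt(1 - ar_phi^2)),
                      n_vol, n_voxels)
      innov[1L, ] <- innov[1L, ] / sqrt(1 - ar_phi^2)  # stationary start
      noise <- t(apply_ar1(innov, ar_phi))
      amp <- stats::rnorm(n_voxels, 0, drift_sd)
      drift <- outer(amp, seq(-0.5, 0.5, length.out = n_vol))
      dat <- noise + drift
      lab <- sig_labels[[b]]$labels
      tid <- sig_labels[[b]]$trial_id
      for (v in which(!is.na(lab))) {
        dat[, v] <- dat[, v] + snr * fidelity[tid[v]] * patterns[, lab[v]]
      }
      blocks[[b]] <- voxel_timeseries(dat, design$tr_seconds,
                                      rep(b, n_vol))
    }
    truth <- new_ground_truth(patterns, support, snr, occupancy, lag,
                              fidelity,
                              noise = list(ar_phi = ar_phi,
                                           drift_sd = drift_sd))
    structure(list(blocks = blocks, labels = labels, truth = truth,
                   design = design, seed = as.integer(seed)),
              class = "ia_subject")
  })
}

# recursive AR(1) filter down the rows (time) of a time x voxel matrix
apply_ar1 <- function(innov, phi) {
  if (phi == 0) return(innov)
  out <- innov
  for (t in 2:nrow(innov)) out[t, ] <- phi * out[t - 1L, ] + innov[t, ]
  out
}

#' @export
print.ia_subject <- function(x, ...) {
  cat(sprintf("<ia_subject> %d voxels, %d blocks, snr = %g, seed = %d\n",
              nrow(x$blocks[[1]]$data), length(x$blocks), x$truth$snr,
              x$seed))
  invisible(x)
}

#' Simulate a meditation run with a known hidden state sequence
#'
#' Generates a breath-focused meditation run: a hidden state sequence over
#' Breath / MW / Self follows a dwell-time chain (geometric dwell above a
#' minimum, mean dwell proportional to the requested occupancy, uniform
#' switching), and every decodable volume emits the subject's corresponding
#' condition pattern at the subject's SNR plus AR(1) noise and drift. The run
#' is split into two blocks (40% / 60%, emulating a 4 + 6 min session); each
#' block is preceded by 8 unlabelled instruction volumes (6 s instruction +
#' 2 s reminder) flagged non-decodable, so decodable volumes equal
#' `n_volumes` exactly. State runs never span the block boundary.
#'
#' @param truth Ground truth from [simulate_subject()] (patterns, SNR,
#'   occupancy).
#' @param n_volumes Decodable volumes (default 600, i.e. 10 min at TR 1 s).
#' @param min_dwell Minimum true dwell length in volumes (default 3).
#' @param seed Integer seed.
#' @param base_dwell Scale of mean dwell in volumes: a state's mean dwell is
#'   `3 * occupancy * base_dwell` (default 12, giving mean dwells of 18/9/9
#'   volumes at 0.5/0.25/0.25 occupancy).
#' @param occupancy Named target occupancy over the three states; defaults to
#'   `truth$occupancy`.
#' @param tr_seconds Sampling interval (default 1 s).
#' @return List of class `meditation_run`: `ts` (a [voxel_timeseries()] with
#'   `decodable` flags and block ids) and `states` (true state per decodable
#'   volume).
#' @export
simulate_meditation <- function(truth, n_volumes = 600L, min_dwell = 3L,
                                seed, base_dwell = 12,
                                occupancy = truth$occupancy,
                                tr_seconds = 1.0) {
  stopifnot(inherits(truth, "ground_truth"))
  if (min_dwell < 1L || n_volumes < min_dwell)
    stop_invalid("need n_volumes >= min_dwell >= 1")
  states <- meditation_states()
  if (!all(names(occupancy) %in% states))
    stop_invalid(sprintf("unknown state(s) in occupancy: %s",
                         paste(setdiff(names(occupancy), states),
                               collapse = ", ")))
  occupancy <- occupancy[states]
  if (anyNA(occupancy) || abs(sum(occupancy) - 1) > 1e-8)
    stop_invalid("occupancy must cover Breath/MW/Self and sum to 1")
  mean_dwell <- 3 * occupancy * base_dwell
  if (any(mean_dwell <= min_dwell))
    stop_invalid("occupancy too small for min_dwell at this base_dwell")

  n_voxels <- nrow(truth$condition_patterns)
  block_len <- c(round(0.4 * n_volumes), n_volumes - round(0.4 * n_volumes))
  n_instr <- 8L  # 6 s instruction + 2 s reminder, modelled up front

  withr::with_seed(as.integer(seed), {
    state_seq <- character(0)
    block_id <- integer(0)
    decodable <- logical(0)
    dat <- NULL
    for (b in seq_along(block_len)) {
      s <- dwell_chain(block_len[b], states, occupancy, mean_dwell, min_dwell)
      n_vol <- n_instr + block_len[b]
      innov <- matrix(stats::rnorm(n_vol * n_voxels,
                                   sd = sqrt(1 - truth$noise$ar_phi^2)),
                      n_vol, n_voxels)
      innov[1L, ] <- innov[1L, ] / sqrt(1 - truth$noise$ar_phi^2)
      noise <- t(apply_ar1(innov, truth$noise$ar_phi))
      amp <- stats::rnorm(n_voxels, 0, truth$noise$drift_sd)
      bdat <- noise + outer(amp, seq(-0.5, 0.5, length.out = n_vol))
      for (v in seq_along(s)) {
        bdat[, n_instr + v] <- bdat[, n_instr + v] +
          truth$snr * truth$condition_patterns[, s[v]]
      }
      dat <- cbind(dat, bdat)
      state_seq <- c(state_seq, s)
      block_id <- c(block_id, rep(b, n_vol))
      decodable <- c(decodable, rep(c(FALSE, TRUE), c(n_instr, block_len[b])))
    }
    list(ts = voxel_timeseries(dat, tr_seconds, block_id, decodable),
         states = state_seq) |>
      structure(class = "meditation_run")
  })
}

# semi-Markov dwell chain: geometric dwell above min_dwell, uniform switch
dwell_chain <- function(n, states, occupancy, mean_dwell, min_dwell) {
  s <- character(0)
  cur <- sample(states, 1L, prob = occupancy)
  while (length(s) < n) {
    p <- 1 / (mean_dwell[cur] - min_dwell + 1)
    d <- min_dwell + stats::rgeom(1L, p)
    s <- c(s, rep(cur, d))
    cur <- sample(setdiff(states, cur), 1L)
  }
  s[seq_len(n)]
}

#' @export
print.meditation_run <- function(x, ...) {
  cat(sprintf("<meditation_run> %d volumes (%d decodable) in %d blocks\n",
              ncol(x$ts$data), sum(x$ts$decodable),
              length(unique(x$ts$block_id))))
  print(round(100 * prop.table(table(x$states)), 1))
  invisible(x)
}

#' Attach subjective attention ratings to a subject's design
#'
#' Ratings (1 = less attention ... 4 = more attention) are attached to every
#' rating-eligible trial (last half of the blocks, never MW): the latent
#' score `coupling * trial_fidelity + noise` is discretized monotonically
#' into within-subject quartiles, so participants use the full 1--4 range.
#' With `coupling = 0` ratings are independent of the emitted signal.
#'
#' @param design The subject's [make_task_design()] object.
#' @param truth Ground truth from [simulate_subject()] (supplies the per-trial
#'   pattern fidelities).
#' @param coupling Weight of true fidelity in the latent score (default 1).
#' @param noise_sd SD of the latent noise (default 0.5).
#' @param seed Integer seed.
#' @return The design with `rating` filled in on eligible trials.
#' @export
simulate_ratings <- function(design, truth, coupling = 1, noise_sd = 0.5,
                             seed) {
  stopifnot(inherits(design, "task_design"), inherits(truth, "ground_truth"))
  ev <- design_events(design)
  eligible <- which(ev$rating_eligible)
  if (!length(eligible)) stop_invalid("design has no rating-eligible trials")
  withr::with_seed(as.integer(seed), {
    latent <- coupling * truth$trial_fidelity[eligible] +
      stats::rnorm(length(eligible), sd = noise_sd)
    rk <- rank(latent, ties.method = "first")
    rating <- as.integer(ceiling(4 * rk / length(rk)))
  })
  i <- 0L
  for (b in seq_along(design$blocks)) {
    tr <- design$blocks[[b]]$trials
    for (j in seq_len(nrow(tr))) {
      i <- i + 1L
      if (i %in% eligible)
        design$blocks[[b]]$trials$rating[j] <- rating[match(i, eligible)]
    }
  }
  design
}
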