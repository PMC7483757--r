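#' Generate a balanced internal-attention task design
#'
#' Builds the block design of the internal-attention (IA) task: by default six
#' blocks, each holding 13 trials (three each of Breath, Feet and Sounds, two
#' each of MW and Self) bracketed by 20 s of baseline at both ends, with a 2 s
#' auditory instruction before every trial. Within every block each condition
#' is labelled for exactly 72 s, so a six-block design yields 432 labelled
#' volumes per condition (2,160 in total at TR = 1 s).
#'
#' Breath/Feet/Sounds trial durations are even numbers of seconds in 16--32;
#' in the default six-block design every even duration is used exactly twice
#' per condition across the experiment, partitioned into per-block triples
#' summing to 72 s by a seeded backtracking search. MW/Self durations are even
#' numbers in 22--50, drawn as per-block pairs summing to 72 s with distinct
#' short members so the durations cover most of the range.
#'
#' Four candidate stimulus orderings ("order sets") are derived from the seed;
#' `order_set` selects one, mirroring randomized presentation orders.
#'
#' Attention ratings (1--4) are collected only in the last half of the blocks
#' and never after MW trials; the design marks those trials as rating-eligible
#' (ratings themselves are attached by [simulate_ratings()]).
#'
#' @param seed Integer seed; identical seeds reproduce identical designs.
#' @param n_blocks Number of task blocks (default 6). For values other than 6
#'   the per-block 72 s balance is kept but the "each duration twice"
#'   experiment-wide constraint is dropped (it is specific to 18 trials).
#' @param order_set Which of the four seeded stimulus orders to use (1--4).
#' @param tr_seconds Sampling interval of the paired fMRI acquisition (s).
#' @return An object of class `task_design`: a list with `blocks` (each a list
#'   with a `trials` data frame and baseline durations), `conditions`,
#'   `tr_seconds`, `n_blocks` and `order_set`.
#' @examples
#' d <- make_task_design(seed = 1)
#' design_condition_seconds(d)  # 72 s per condition per block
#' @export
make_task_design <- function(seed, n_blocks = 6L, order_set = 1L,
                             tr_seconds = 1.0) {
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1)
    stop_invalid("n_blocks must be a positive integer")
  n_blocks <- as.integer(n_blocks)
  if (!order_set %in% 1:4)
    stop_invalid("order_set must be in 1..4")
  if (tr_seconds <= 0) stop_invalid("tr_seconds must be positive")

  withr::with_seed(as.integer(seed), {
    short_durs <- lapply(c(Breath = 1, Feet = 2, Sounds = 3), function(i) {
      if (n_blocks == 6L) {
        partition_into_triples(rep(seq(16L, 32L, 2L), 2L), target = 72L)
      } else {
        replicate(n_blocks, random_triple_72(), simplify = FALSE)
      }
    })
    long_durs <- lapply(c(MW = 1, Self = 2), function(i) {
      if (n_blocks == 6L) {
        short <- sample(seq(22L, 36L, 2L), 6L)   # distinct short pair members
        lapply(short[sample.int(6L)], function(d) sample(c(d, 72L - d)))
      } else {
        replicate(n_blocks, {
          d <- sample(seq(22L, 50L, 2L), 1L)
          sample(c(d, 72L - d))
        }, simplify = FALSE)
      }
    })

    trial_mix <- rep(c("Breath", "Feet", "Sounds", "MW", "Self"),
                     times = c(3L, 3L, 3L, 2L, 2L))
    order_sets <- lapply(1:4, function(i)
      lapply(seq_len(n_blocks), function(b) sample(trial_mix)))
    orders <- order_sets[[order_set]]

    blocks <- lapply(seq_len(n_blocks), function(b) {
      seq_in_block <- orders[[b]]
      pools <- c(lapply(short_durs, function(x) x[[b]]),
                 lapply(long_durs, function(x) x[[b]]))
      taken <- stats::setNames(integer(5L), names(pools))
      onset <- 20  # leading baseline
      rows <- vector("list", length(seq_in_block))
      for (i in seq_along(seq_in_block)) {
        cond <- seq_in_block[i]
        taken[cond] <- taken[cond] + 1L
        dur <- pools[[cond]][taken[cond]]
        onset <- onset + 2  # auditory instruction, unlabelled
        rows[[i]] <- data.frame(condition = cond, onset_seconds = onset,
                                duration_seconds = dur)
        onset <- onset + dur
      }
      trials <- do.call(rbind, rows)
      trials$rating <- NA_integer_
      trials$rating_eligible <- b > n_blocks / 2 & trials$condition != "MW"
      list(trials = trials,
           baseline_pre_seconds = 20,
           baseline_post_seconds = 20,
           duration_seconds = onset + 20)
    })

    structure(list(blocks = blocks, conditions = ia_conditions(),
                   tr_seconds = tr_seconds, n_blocks = n_blocks,
                   order_set = as.integer(order_set), seed = as.integer(seed)),
              class = "task_design")
  })
}

# Partition a multiset of durations into triples with a common target sum by
# randomized backtracking. Node budget guards against infeasible inputs.
partition_into_triples <- function(durs, target, max_nodes = 200000L) {
  if (length(durs) %% 3L != 0L || sum(durs) != target * length(durs) / 3L)
    stop(errorCondition("duration multiset cannot balance into equal-sum triples",
                        class = c("iastates_infeasible_design", "error")))
  k <- length(durs) %/% 3L
  ord <- order(-durs, sample.int(length(durs)))  # desc, random tie order
  durs <- durs[ord]
  sums <- integer(k); counts <- integer(k)
  assign <- integer(length(durs))
  nodes <- 0L

  vmin <- min(durs); vmax <- max(durs)
  rec <- function(i) {
    if (i > length(durs)) return(TRUE)
    d <- durs[i]
    tried_empty <- FALSE  # empty slots are interchangeable; try only one
    for (j in sample.int(k)) {
      if (counts[j] >= 3L) next
      if (counts[j] == 0L) {
        if (tried_empty) next
        tried_empty <- TRUE
      }
      nodes <<- nodes + 1L
      if (nodes > max_nodes)
        stop(errorCondition("balanced triple partition search exceeded budget",
                            class = c("iastates_infeasible_design", "error")))
      s <- sums[j] + d
      rest <- target - s          # sum still needed in this slot
      left <- 2L - counts[j]      # values still to add after d
      if (rest < left * vmin || rest > left * vmax) next
      sums[j] <<- s; counts[j] <<- counts[j] + 1L; assign[i] <<- j
      if (rec(i + 1L)) return(TRUE)
      sums[j] <<- sums[j] - d; counts[j] <<- counts[j] - 1L
    }
    FALSE
  }
  if (!rec(1L))
    stop(errorCondition("no balanced triple partition exists",
                        class = c("iastates_infeasible_design", "error")))
  lapply(seq_len(k), function(j) sample(durs[assign == j]))
}

# A random triple of even durations in [16, 32] summing to 72 s.
random_triple_72 <- function() {
  d1 <- sample(seq(16L, 32L, 2L), 1L)
  lo <- max(16L, 72L - d1 - 32L); hi <- min(32L, 72L - d1 - 16L)
  d2 <- sample(seq(lo, hi, 2L), 1L)
  sample(c(d1, d2, 72L - d1 - d2))
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d blocks, %d trials/block, TR = %g s, order set %d\n",
              x$n_blocks, nrow(x$blocks[[1]]$trials), x$tr_seconds, x$order_set))
  secs <- design_condition_seconds(x)
  cat("labelled seconds per condition per block:\n")
  print(secs)
  invisible(x)
}

#' Flatten a task design into a BIDS-style events table
#'
#' @param design A [make_task_design()] object.
#' @return A data frame with columns `block`, `trial`, `onset`, `duration`,
#'   `trial_type`, `rating` (one row per trial; onsets are within-block
#'   seconds, 0-based). `trial` is a design-wide trial index.
#' @export
design_events <- function(design) {
  stopifnot(inherits(design, "task_design"))
  out <- do.call(rbind, lapply(seq_along(design$blocks), function(b) {
    tr <- design$blocks[[b]]$trials
    data.frame(block = b, onset = tr$onset_seconds,
               duration = tr$duration_seconds, trial_type = tr$condition,
               rating = tr$rating, rating_eligible = tr$rating_eligible)
  }))
  out <- cbind(block = out$block, trial = seq_len(nrow(out)),
               out[, -1, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Labelled seconds per condition per block
#'
#' @param design A [make_task_design()] object.
#' @return Matrix (blocks x conditions) of summed trial seconds.
#' @export
design_condition_seconds <- function(design) {
  stopifnot(inherits(design, "task_design"))
  m <- t(vapply(design$blocks, function(b) {
    vapply(design$conditions, function(cond)
      sum(b$trials$duration_seconds[b$trials$condition == cond]), numeric(1))
  }, stats::setNames(numeric(5), design$conditions)))
  rownames(m) <- paste0("block", seq_len(nrow(m)))
  m
}
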