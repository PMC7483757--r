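test_that("singleton smoothing follows the worked flanking examples", {
  x <- c("MW", "MW", "MW", "Self", "MW", "MW", "MW")
  sm <- smooth_decisions(x)
  expect_equal(sm$decisions, rep("MW", 7))
  expect_equal(sm$pct_smoothed, 100 / 7, tolerance = 1e-10)
  # no singleton runs: unchanged
  y <- c("Breath", "Breath", "MW", "MW")
  expect_equal(smooth_decisions(y)$decisions, y)
  expect_equal(smooth_decisions(y)$pct_smoothed, 0)
  # all singletons: flanks too short under min_flank = 2
  z <- c("Breath", "Self", "Breath")
  expect_equal(smooth_decisions(z)$decisions, z)
  # flanks of length 1 do not trigger relabelling
  w <- c("MW", "Self", "MW", "MW")
  expect_equal(smooth_decisions(w)$decisions, w)
  # a block boundary between the flanks blocks the merge
  b <- c("MW", "MW", "Self", "MW", "MW")
  expect_equal(smooth_decisions(b)$decisions, rep("MW", 5))
  expect_equal(smooth_decisions(b, block_id = c(1, 1, 1, 2, 2))$decisions, b)
})

test_that("event extraction follows the run-length worked examples", {
  x <- c("S", "S", "S", "S", "B", "B", "M", "M", "M")
  ee <- extract_events(x)
  expect_equal(ee$events$state, c("S", "M"))
  expect_equal(ee$events$n_volumes, c(4L, 3L))
  expect_equal(ee$events$onset_seconds, c(0, 6))
  expect_equal(ee$pct_excluded, 100 * 2 / 9, tolerance = 1e-10)
  # one long run: a single event, nothing excluded
  all_b <- rep("Breath", 600)
  e2 <- extract_events(all_b)
  expect_equal(nrow(e2$events), 1L)
  expect_equal(e2$events$duration_seconds, 600)
  expect_equal(e2$pct_excluded, 0)
  # strict alternation: no events at all
  alt <- rep(c("Breath", "MW"), 50)
  e3 <- extract_events(alt)
  expect_equal(nrow(e3$events), 0L)
  expect_equal(e3$pct_excluded, 100)
  # runs are cut at the block boundary
  xb <- rep("Breath", 6)
  e4 <- extract_events(xb, block_id = c(1, 1, 1, 1, 2, 2))
  expect_equal(e4$events$n_volumes, 4L)
  expect_equal(e4$pct_excluded, 100 * 2 / 6)
})

test_that("smoothing and extraction match the brute-force reference", {
  withr::with_seed(13, {
    for (i in 1:500) {
      n <- sample(1:50, 1)
      x <- sample(meditation_states(), n, replace = TRUE)
      blocks <- if (i %% 3 == 0) sort(sample(1:2, n, replace = TRUE))
                else rep(1L, n)
      sm <- smooth_decisions(x, block_id = blocks)
      ref <- oracle_smooth(x, block_id = blocks)
      expect_identical(sm$decisions, ref$decisions)
      expect_identical(sm$n_smoothed, ref$n_smoothed)
      ee <- extract_events(sm$decisions, block_id = blocks)
      re <- oracle_events(sm$decisions, block_id = blocks)
      expect_identical(ee$events$state, re$events$state)
      expect_identical(ee$events$n_volumes, re$events$n_volumes)
      expect_identical(as.integer(ee$events$onset_seconds), re$events$onset)
      expect_equal(ee$pct_excluded, 100 * re$excluded / n)
      # conservation: event volumes + excluded volumes = total
      expect_equal(sum(ee$events$n_volumes) +
                     round(n * ee$pct_excluded / 100), n)
    }
  })
})

test_that("iterative smoothing is a documented superset of the single pass", {
  x <- c("MW", "MW", "Self", "MW", "MW", "Self", "MW", "MW")
  once <- smooth_decisions(x)
  again <- smooth_decisions(x, iterative = TRUE)
  expect_gte(again$n_smoothed, once$n_smoothed)
  expect_equal(again$decisions, rep("MW", 8))
})

test_that("meditation decoding is restricted to the three states", {
  s <- small_subject()
  full <- concat_blocks(lapply(s$blocks, detrend_linear),
                        lapply(s$labels, shift_labels))
  m <- train_classifier(full$ts, full$labels)
  med <- simulate_meditation(s$truth, seed = 23)
  run <- decode_meditation(m, med$ts)
  expect_equal(run$n_volumes, 600L)
  expect_false(any(run$raw_decisions %in% c("Feet", "Sounds")))
  expect_equal(colnames(run$evidence), meditation_states())
  expect_true(all(run$evidence > 0 & run$evidence < 1))
  # events cover their own volumes in the smoothed decisions
  for (j in seq_len(nrow(run$events))) {
    ev <- run$events[j, ]
    vols <- (ev$onset_seconds + 1):(ev$onset_seconds + ev$n_volumes)
    expect_true(all(run$smoothed_decisions[vols] == ev$state))
  }
  # conservation of volumes
  expect_equal(sum(run$events$n_volumes) +
                 round(run$n_volumes * run$pct_excluded / 100),
               run$n_volumes)
  # voxel-grid mismatch is a shape error
  expect_error(decode_run(m, voxel_timeseries(matrix(0.0, 3, 10), 1)),
               class = "iastates_shape_error")
})

test_that("a pure-breath run decodes overwhelmingly to Breath", {
  for (sd in 1:3) {
    s <- simulate_subject(default_design(), n_voxels = 60, snr = 2,
                          seed = 30 + sd)
    full <- concat_blocks(lapply(s$blocks, detrend_linear),
                          lapply(s$labels, shift_labels))
    m <- train_classifier(full$ts, full$labels)
    withr::with_seed(40 + sd, {
      noise <- matrix(rnorm(60 * 100), 60, 100)
    })
    run_dat <- noise + 2 * s$truth$condition_patterns[, "Breath"]
    dec <- decode_run(m, voxel_timeseries(run_dat, 1))
    expect_gte(mean(dec$decisions == "Breath"), 0.95)
  }
})
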