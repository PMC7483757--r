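# a minimal hand-built classifier on a known grid
fake_model <- function(weights) {
  structure(list(weights = weights,
                 intercepts = setNames(rep(0, nrow(weights)),
                                       rownames(weights)),
                 penalty = 0.01, condition_order = rownames(weights),
                 training_volume_count = 0L, standardize = FALSE),
            class = "ia_classifier")
}

test_that("importance is weight times z-scored condition activation", {
  # 2 voxels, 8 volumes: voxel 1 activates during A, voxel 2 is flat
  lab <- c("A", "A", "B", "B", "A", "A", "B", "B")
  dat <- rbind(c(1, 1, -1, -1, 1, 1, -1, -1),
               rep(0.5, 8))
  w <- rbind(A = c(0.5, 0.4), B = c(-0.2, 0))
  m <- fake_model(w)
  imap <- compute_importance(m, dat, lab, "A")
  # voxel 1: z-scored series is +-~1 during A, weight +0.5 -> positive
  expect_gt(imap$importance[1], 0)
  expect_equal(imap$class[1], "positive")
  expect_equal(imap$importance[1], 0.5 * imap$activation[1])
  # voxel 2: zero-variance series -> zero activation -> class none
  expect_equal(imap$importance[2], 0)
  expect_equal(imap$class[2], "none")
  # for B, voxel 1 has negative weight and negative activation -> negative
  imap_b <- compute_importance(m, dat, lab, "B")
  expect_equal(imap_b$class[1], "negative")
  # mixed sign (positive weight, negative activation) -> none
  imap_mix <- compute_importance(fake_model(rbind(A = c(0.5, 0.1),
                                                  B = c(0.5, 0.1))),
                                 dat, lab, "B")
  expect_equal(imap_mix$class[1], "none")
  # all-zero weights -> all zero importance, all none
  z <- compute_importance(fake_model(rbind(A = c(0, 0), B = c(0, 0))),
                          dat, lab, "A")
  expect_true(all(z$importance == 0))
  expect_true(all(z$class == "none"))
  expect_error(compute_importance(m, dat, lab, "C"),
               class = "iastates_missing_class")
  expect_error(compute_importance(m, dat, rep("B", 8), "A"),
               class = "iastates_missing_class")
})

test_that("thresholding retains the ~4.55% Gaussian tail at 2 SD", {
  withr::with_seed(8, imp <- rnorm(200000))
  map <- structure(data.frame(voxel = seq_along(imp), weight = sign(imp),
                              activation = abs(imp), importance = imp,
                              class = ifelse(imp > 0, "positive",
                                             "negative")),
                   condition = "Breath",
                   class = c("importance_map", "data.frame"))
  th <- threshold_map(map)
  frac <- 100 * mean(th$retained)
  expect_equal(frac, 100 * 2 * pnorm(-2), tolerance = 0.1)
  expect_true(all(abs(th$z[th$retained]) >= 2))
  # identical importances: zero variance, empty set with warning
  flat <- map; flat$importance <- rep(1, nrow(flat))
  expect_warning(thf <- threshold_map(flat), "zero variance")
  expect_false(any(thf$retained))
})

test_that("frequency maps count subjects per voxel, pooled = pos + neg", {
  mk <- function(retained, cls) {
    structure(data.frame(voxel = seq_along(retained),
                         weight = 0, activation = 0, importance = 0,
                         class = cls, z = 0, retained = retained),
              condition = "Breath",
              class = c("importance_map", "data.frame"))
  }
  m1 <- mk(c(TRUE, FALSE, TRUE), c("positive", "none", "negative"))
  m2 <- mk(c(FALSE, FALSE, TRUE), c("none", "none", "positive"))
  m3 <- mk(c(TRUE, FALSE, FALSE), c("negative", "none", "none"))
  fm <- frequency_map(list(m1, m2, m3))
  expect_equal(fm, c(2L, 0L, 2L))
  expect_true(all(fm <= 3))
  expect_equal(frequency_map(list(m1, m2, m3), sign = "positive") +
                 frequency_map(list(m1, m2, m3), sign = "negative"), fm)
  expect_equal(frequency_map(list()), integer(0))
  expect_error(frequency_map(list(m1, mk(TRUE, "positive"))),
               class = "iastates_shape_error")
})

test_that("mask fractions count retained voxels inside the mask", {
  map <- structure(data.frame(voxel = 1:6, weight = 1, activation = 1,
                              importance = 1, class = "positive", z = 3,
                              retained = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                           FALSE)),
                   class = c("importance_map", "data.frame"))
  expect_equal(mask_fraction(map, rep(TRUE, 6)), 100)
  expect_equal(mask_fraction(map, c(FALSE, FALSE, FALSE, FALSE, TRUE,
                                    TRUE)), 0)
  expect_equal(mask_fraction(map, c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                    FALSE)), 50)
  none <- map; none$retained <- FALSE
  expect_true(is.na(mask_fraction(none, rep(TRUE, 6))))
  expect_error(mask_fraction(map, TRUE), class = "iastates_shape_error")
})

test_that("thresholded maps recover the planted pattern support", {
  d <- default_design()
  s <- simulate_subject(d, n_voxels = 150, snr = 2, seed = 17)
  full <- concat_blocks(lapply(s$blocks, detrend_linear),
                        lapply(s$labels, shift_labels))
  m <- train_classifier(full$ts, full$labels)
  imap <- threshold_map(compute_importance(m, full$ts, full$labels,
                                           "Breath"))
  hit <- sum(imap$retained & seq_len(150) %in%
               s$truth$pattern_support$Breath)
  n_ret <- sum(imap$retained)
  k <- length(s$truth$pattern_support$Breath)
  expect_gt(n_ret, 0)
  # overlap above chance: hypergeometric upper tail
  p <- phyper(hit - 1, k, 150 - k, n_ret, lower.tail = FALSE)
  expect_lt(p, 0.01)
})
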