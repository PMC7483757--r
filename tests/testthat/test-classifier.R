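test_that("ridge logistic matches direct likelihood maximization on a toy set", {
  withr::with_seed(11, {
    X <- matrix(rnorm(20 * 2), 20, 2)
    y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(20, sd = 0.5) > 0)
  })
  lam <- 0.01
  fit <- iastates:::ridge_logistic(X, y, lambda = lam)
  ref <- optim(rep(0, 3), pen_loglik, X = X, y = y, lambda = lam,
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(c(fit$b, fit$w), ref$par, tolerance = 1e-4)
  # and the resulting decisions agree on fresh points
  withr::with_seed(12, Xn <- matrix(rnorm(50 * 2), 50, 2))
  expect_identical(drop(cbind(1, Xn) %*% c(fit$b, fit$w)) > 0,
                   drop(cbind(1, Xn) %*% ref$par) > 0)
})

test_that("ridge logistic agrees with glmnet under the lambda mapping", {
  skip_if_not_installed("glmnet")
  withr::with_seed(21, {
    X <- matrix(rnorm(200 * 8), 200, 8)
    y <- as.numeric(drop(X %*% c(1, -1, rep(0.2, 6))) + rnorm(200) > 0)
  })
  lam <- 0.5  # appreciable penalty so the mapping actually matters
  fit <- iastates:::ridge_logistic(X, y, lambda = lam, tol = 1e-9)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 2 * lam / length(y), standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$w), as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(fit$b, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("training yields five one-vs-rest models with the stated defaults", {
  s <- small_subject()
  full <- concat_blocks(lapply(s$blocks, detrend_linear),
                        lapply(s$labels, shift_labels))
  m <- train_classifier(full$ts, full$labels)
  expect_s3_class(m, "ia_classifier")
  expect_equal(m$penalty, 0.01)
  expect_equal(dim(m$weights), c(5L, 60L))
  expect_equal(m$condition_order, ia_conditions())
  expect_equal(m$training_volume_count, 2160L)
  expect_true(m$converged)
  ev <- predict_evidence(m, full$ts)
  expect_true(all(ev > 0 & ev < 1))
  expect_equal(dim(ev), c(ncol(full$ts$data), 5L))
  # deterministic refit
  m2 <- train_classifier(full$ts, full$labels)
  expect_equal(m$weights, m2$weights, tolerance = 1e-12)
  # a condition missing from the labels is a missing-class error
  lab_nofeet <- full$labels
  lab_nofeet$labels[lab_nofeet$labels == "Feet"] <- NA
  expect_error(train_classifier(full$ts, lab_nofeet),
               class = "iastates_missing_class")
})

test_that("decisions are the evidence argmax with ordered tie-breaking", {
  ev <- rbind(c(0.7, 0.1, 0.1, 0.05, 0.05),
              c(0.1, 0.6, 0.3, 0.2, 0.1))
  colnames(ev) <- ia_conditions()
  expect_equal(decide(ev), c("Breath", "Feet"))
  tie <- rbind(c(0.5, 0.5, 0.1, 0.1, 0.1))
  colnames(tie) <- ia_conditions()
  expect_warning(dec <- decide(tie), "tied")
  expect_equal(dec, "Breath")
  expect_length(decide(ev, allowed = c("MW", "Self")), 2L)
  expect_true(all(decide(ev, allowed = c("MW", "Self")) %in%
                    c("MW", "Self")))
  expect_error(decide(ev, allowed = character(0)),
               class = "iastates_invalid_argument")
})

test_that("leave-one-block-out cross-validation partitions the volumes", {
  cv <- small_cv()
  expect_equal(nrow(cv$decisions), 2160L)
  expect_equal(cv$fold_train_counts, rep(1800L, 6))
  # every labelled volume tested exactly once
  key <- paste(cv$decisions$block, cv$decisions$volume)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(as.vector(table(cv$decisions$block)), rep(360L, 6))
  # per-condition test counts are 432 each
  expect_equal(as.vector(table(cv$decisions$truth)), rep(432L, 5))
  expect_error(cross_validate(small_subject()$blocks[1],
                              small_subject()$labels[1]),
               class = "iastates_invalid_argument")
})

test_that("high-snr subjects are classified above 90% in every condition", {
  accs <- sapply(c(7, 8, 9), function(sd) {
    s <- simulate_subject(default_design(), n_voxels = 60, snr = 2,
                          seed = sd)
    evaluate_decisions(crossval_subject(s))$accuracy
  })
  expect_true(all(accs > 90))
})

test_that("accuracy reports carry the chi-square inclusion rule", {
  cv <- small_cv()
  rep <- evaluate_decisions(cv)
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 100))
  expect_equal(unname(rowSums(rep$confusion)), rep(432L, 5))
  expect_equal(sum(rep$confusion), 2160L)
  expect_true(rep$included)  # high-snr subject passes the 2-of-3 rule
  # hand-computed goodness of fit: 130 correct of 432 vs expected 86.4/345.6
  dec <- c(rep("Breath", 130), rep("Feet", 302))
  tru <- rep("Breath", 432)
  ct <- suppressWarnings(chisq.test(c(130, 302), p = c(0.2, 0.8)))
  expect_equal(unname(ct$statistic), 27.5, tolerance = 0.01)
  r2 <- evaluate_decisions(c(dec, "Feet", "MW", "Self", "Sounds"),
                           c(tru, "Feet", "MW", "Self", "Sounds"))
  expect_equal(r2$chisq$statistic[r2$chisq$condition == "Breath"],
               unname(ct$statistic), tolerance = 1e-8)
  expect_lt(r2$chisq$p[r2$chisq$condition == "Breath"], 0.001)
  # all-correct decisions: perfect diagonal report
  perf <- evaluate_decisions(cv$decisions$truth, cv$decisions$truth)
  expect_true(all(perf$accuracy == 100))
  expect_true(all(perf$confusion[upper.tri(perf$confusion)] == 0))
  expect_true(all(perf$chisq$p < 0.001))
  expect_error(evaluate_decisions(rep("Breath", 5), rep("Breath", 5)),
               class = "iastates_undefined_accuracy")
})

test_that("group accuracy t-test degenerates to 0 at exact chance", {
  acc <- matrix(20, 4, 5, dimnames = list(NULL, ia_conditions()))
  g <- group_accuracy_test(acc)
  expect_true(all(g$t == 0))
  expect_true(all(g$cohens_d == 0))
  # percent and proportion scales give the same t
  withr::with_seed(5, a <- matrix(runif(20, 30, 60), 4, 5,
                                  dimnames = list(NULL, ia_conditions())))
  expect_equal(group_accuracy_test(a)$t, group_accuracy_test(a / 100)$t)
})

test_that("rating correlations use Fisher z and handle degenerate subjects", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # two subjects with mirrored correlations: mean z = 0, t = 0
  s1 <- data.frame(subject = 1, condition = "Breath",
                   accuracy = c(0.2, 0.4, 0.6, 0.8), rating = c(1, 2, 4, 3))
  s2 <- s1; s2$subject <- 2; s2$rating <- rev(s2$rating)
  rc <- rating_correlation(rbind(s1, s2))
  expect_equal(rc$per_subject$r[1], -rc$per_subject$r[2])
  expect_equal(rc$mean_z, 0, tolerance = 1e-10)
  expect_equal(rc$t, 0, tolerance = 1e-10)
  # z equals atanh(r) for a constructed in-between subject
  s3 <- data.frame(subject = 3, condition = "Breath",
                   accuracy = c(0.1, 0.5, 0.3, 0.9),
                   rating = c(1, 3, 4, 2))
  rc3 <- rating_correlation(rbind(s1, s2, s3))
  r3 <- cor(s3$accuracy, s3$rating)
  expect_equal(rc3$per_subject$z[rc3$per_subject$subject == 3], atanh(r3))
  # constant ratings: undefined r, dropped with a warning
  s4 <- s1; s4$subject <- 4; s4$rating <- 2
  expect_warning(rc4 <- rating_correlation(rbind(s1, s2, s4)), "dropped")
  expect_equal(rc4$n_dropped, 1L)
  # MW trials are excluded by construction
  mw <- data.frame(subject = 1, condition = "MW", accuracy = 1, rating = 4)
  expect_equal(rating_correlation(rbind(s1, s2, mw))$mean_z, rc$mean_z)
})

test_that("accuracy correlates with ratings for an attentive subject", {
  s <- small_subject()
  cv <- small_cv()
  rated <- simulate_ratings(s$design, s$truth, coupling = 5,
                            noise_sd = 0.01, seed = 31)
  ta <- trial_accuracies(cv, rated)
  ta$subject <- 1
  rated_trials <- ta[!is.na(ta$rating), ]
  expect_equal(nrow(rated_trials), 33L)
  expect_gt(cor(rated_trials$accuracy, rated_trials$rating), 0)
})
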