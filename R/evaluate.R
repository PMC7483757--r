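#' Score cross-validated decisions against true labels
#'
#' Computes per-condition accuracy (percent of that condition's tested
#' volumes decided correctly), the full confusion matrix, a per-condition
#' chi-square goodness-of-fit test of correct vs. incorrect counts against
#' the 1-in-5 chance split (expected 0.2/0.8 of the tested count, i.e.
#' 86.4 vs. 345.6 for 432 decisions), and the subject-inclusion flag:
#' a subject is retained for meditation decoding when at least two of the
#' three meditation-relevant conditions (Breath, MW, Self) are classified
#' above chance at chi-square p < 0.001.
#'
#' @param decisions Character vector of decisions, or a `crossval_result`
#'   (in which case `truth` is taken from it).
#' @param truth Character vector of true condition labels, same length.
#' @param conditions Condition set (canonical order).
#' @param chance Chance proportion (default 1 / number of conditions).
#' @param inclusion_alpha Significance level for the inclusion rule
#'   (default 0.001).
#' @param inclusion_conditions Conditions entering the inclusion rule.
#' @return An object of class `accuracy_report`: per-condition `accuracy`
#'   (percent), `confusion` (true x decided counts), `chisq` data frame
#'   (statistic, p, above-chance flag), and `included`.
#' @export
evaluate_decisions <- function(decisions, truth = NULL,
                               conditions = ia_conditions(),
                               chance = 1 / length(conditions),
                               inclusion_alpha = 0.001,
                               inclusion_conditions = meditation_states()) {
  if (inherits(decisions, "crossval_result")) {
    truth <- decisions$decisions$truth
    conditions <- decisions$conditions
    decisions <- decisions$decisions$decision
  }
  if (length(decisions) != length(truth))
    stop_shape("decisions and truth must have the same length")
  truth_f <- factor(truth, levels = conditions)
  dec_f <- factor(decisions, levels = conditions)
  confusion <- table(truth = truth_f, decision = dec_f)
  tested <- rowSums(confusion)
  if (any(tested == 0))
    stop(errorCondition(
      sprintf("no tested volumes for condition(s): %s",
              paste(conditions[tested == 0], collapse = ", ")),
      class = c("iastates_undefined_accuracy", "error")))
  correct <- diag(confusion)
  accuracy <- 100 * correct / tested
  chisq <- do.call(rbind, lapply(seq_along(conditions), function(i) {
    ct <- suppressWarnings(
      stats::chisq.test(c(correct[i], tested[i] - correct[i]),
                        p = c(chance, 1 - chance)))
    data.frame(condition = conditions[i], n_tested = as.integer(tested[i]),
               n_correct = as.integer(correct[i]),
               statistic = unname(ct$statistic), p = unname(ct$p.value),
               above_chance = correct[i] > chance * tested[i])
  }))
  rownames(chisq) <- NULL
  rel <- chisq[chisq$condition %in% inclusion_conditions, ]
  included <- sum(rel$p < inclusion_alpha & rel$above_chance) >= 2L
  structure(list(accuracy = accuracy, confusion = confusion, chisq = chisq,
                 included = included, chance_pct = 100 * chance),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(round(x$accuracy, 1))
  cat(sprintf("included for meditation decoding: %s\n", x$included))
  invisible(x)
}

#' Group-level accuracy test against chance
#'
#' One-sample two-sided t-test of per-subject accuracies against the chance
#' level (20% for five conditions), with Cohen's d, per condition. The test
#' is scale-invariant, so percent and proportion inputs give identical t and
#' d; results are reported on the percent scale.
#'
#' @param accuracies Numeric matrix, subjects x conditions (percent).
#' @param chance Chance accuracy in percent (default 20).
#' @return Data frame: condition, mean accuracy, t, df, p, cohens_d.
#' @export
group_accuracy_test <- function(accuracies, chance = 20) {
  accuracies <- as.matrix(accuracies)
  if (max(accuracies, na.rm = TRUE) <= 1 && chance == 20)
    accuracies <- 100 * accuracies  # proportion input; same t either way
  out <- do.call(rbind, lapply(colnames(accuracies), function(cond) {
    a <- accuracies[, cond]
    s <- stats::sd(a)
    if (s == 0) {
      tt <- list(statistic = 0, parameter = length(a) - 1,
                 p.value = if (mean(a) == chance) 1 else 0)
      d <- if (mean(a) == chance) 0 else Inf * sign(mean(a) - chance)
    } else {
      tt <- stats::t.test(a, mu = chance)
      d <- (mean(a) - chance) / s
    }
    data.frame(condition = cond, mean_accuracy = mean(a),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value), cohens_d = d)
  }))
  rownames(out) <- NULL
  out
}

#' Trial-level accuracy from cross-validated decisions
#'
#' For every trial, the fraction of its (hemodynamically shifted) labelled
#' volumes that were decided correctly, merged with the design's trial table
#' (condition, block, rating eligibility, rating).
#'
#' @param cv A `crossval_result`.
#' @param design The [make_task_design()] the data came from.
#' @return Data frame: trial, block, condition, rating_eligible, rating,
#'   n_volumes, accuracy (0--1).
#' @export
trial_accuracies <- function(cv, design) {
  stopifnot(inherits(cv, "crossval_result"), inherits(design, "task_design"))
  d <- cv$decisions[!is.na(cv$decisions$trial_id), ]
  acc <- stats::aggregate(list(accuracy = d$decision == d$truth,
                               n_volumes = rep(1L, nrow(d))),
                          by = list(trial = d$trial_id),
                          FUN = function(x) sum(x))
  acc$accuracy <- acc$accuracy / acc$n_volumes
  ev <- design_events(design)
  out <- merge(ev[, c("trial", "block", "trial_type", "rating_eligible",
                      "rating")],
               acc, by = "trial")
  names(out)[names(out) == "trial_type"] <- "condition"
  out[order(out$trial), ]
}

#' Within-subject correlation of trial accuracy and attention ratings
#'
#' Per subject, Pearson's r between trial-level classifier accuracy and the
#' subjective attention rating (1--4) over rated trials (MW trials carry no
#' rating by design). Each r is Fisher z-transformed (z = atanh(r)) and the
#' group mean z is tested against 0 with a one-sample two-sided t-test.
#' Subjects with fewer than 3 rated trials in scope, or with zero variance
#' in either variable, have undefined r and are dropped with a warning.
#'
#' @param trials Data frame with columns `subject`, `condition`, `accuracy`,
#'   `rating` (one row per rated trial; rows with `NA` rating are ignored).
#' @param scope `"all"` (every rated condition) or `"breath"` (Breath trials
#'   only).
#' @return List with `per_subject` (subject, n, r, z), `mean_z`, `t`, `df`,
#'   `p`, and `n_dropped`.
#' @export
rating_correlation <- function(trials, scope = c("all", "breath")) {
  scope <- match.arg(scope)
  tr <- trials[!is.na(trials$rating) & trials$condition != "MW", ]
  if (scope == "breath") tr <- tr[tr$condition == "Breath", ]
  per <- do.call(rbind, lapply(split(tr, tr$subject), function(s) {
    r <- if (nrow(s) < 3L || stats::sd(s$accuracy) == 0 ||
             stats::sd(s$rating) == 0) NA_real_
         else stats::cor(s$accuracy, s$rating)
    data.frame(subject = s$subject[1], n = nrow(s), r = r, z = atanh(r))
  }))
  rownames(per) <- NULL
  dropped <- sum(is.na(per$r))
  if (dropped > 0)
    warning(sprintf("%d subject(s) with undefined correlation dropped from the group test",
                    dropped))
  z <- per$z[is.finite(per$z)]
  if (length(z) < 2L)
    stop_invalid("need at least 2 subjects with defined correlations")
  if (stats::sd(z) == 0) {
    tt <- list(statistic = if (mean(z) == 0) 0 else Inf * sign(mean(z)),
               parameter = length(z) - 1,
               p.value = if (mean(z) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(z, mu = 0)
  }
  list(per_subject = per, mean_z = mean(z), t = unname(tt$statistic),
       df = unname(tt$parameter), p = unname(tt$p.value),
       n_dropped = dropped)
}
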