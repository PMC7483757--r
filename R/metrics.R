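#' Per-subject attention metrics from a decoded meditation run
#'
#' For each state: percentage of time engaged (event volumes over all
#' decodable volumes by default, so state percentages plus the excluded
#' percentage sum to exactly 100), number of events, and mean and sample SD
#' (n - 1) of event durations. States with no events get 0% time, 0 events
#' and missing durations; a single event yields a missing SD.
#'
#' @param run A `decoded_run` from [decode_meditation()].
#' @param states States to report (default the run's own).
#' @param denominator `"decodable"` (default: all decodable volumes) or
#'   `"events"` (volumes inside events only).
#' @return Object of class `attention_metrics`: data frame `states` (state,
#'   pct_time, n_events, mean_duration, sd_duration) plus `total_events` and
#'   `pct_excluded`.
#' @export
compute_metrics <- function(run, states = NULL,
                            denominator = c("decodable", "events")) {
  stopifnot(inherits(run, "decoded_run"))
  denominator <- match.arg(denominator)
  if (is.null(states)) states <- run$states
  ev <- run$events
  denom <- switch(denominator,
                  decodable = run$n_volumes,
                  events = max(sum(ev$n_volumes), 1L))
  per <- do.call(rbind, lapply(states, function(s) {
    e <- ev[ev$state == s, ]
    data.frame(state = s,
               pct_time = 100 * sum(e$n_volumes) / denom,
               n_events = nrow(e),
               mean_duration = if (nrow(e)) mean(e$duration_seconds)
                               else NA_real_,
               sd_duration = if (nrow(e) >= 2L) stats::sd(e$duration_seconds)
                             else NA_real_)
  }))
  rownames(per) <- NULL
  structure(list(states = per, total_events = nrow(ev),
                 pct_excluded = run$pct_excluded,
                 denominator = denominator),
            class = "attention_metrics")
}

#' @export
print.attention_metrics <- function(x, ...) {
  cat(sprintf("<attention_metrics> %d events, %.1f%% of volumes excluded\n",
              x$total_events, x$pct_excluded))
  print(x$states, digits = 3)
  invisible(x)
}

#' Group-level contrasts of attention metrics across states
#'
#' For each metric, a one-way repeated-measures ANOVA over the three states
#' (subject as the error stratum) followed by planned paired two-sided
#' t-tests of Breath vs. MW and Breath vs. Self. Subjects with a missing
#' value for the metric in any state (e.g. missing duration SD for
#' single-event states) are dropped from that metric's tests, with the count
#' reported.
#'
#' @param metrics_list List of [compute_metrics()] results, one per subject.
#' @param metrics Metric columns to test.
#' @return Object of class `group_metrics_result`: one row per metric with
#'   F, df, p, the two paired t statistics with dfs and ps, and the number
#'   of subjects excluded for missingness.
#' @export
group_tests <- function(metrics_list,
                        metrics = c("pct_time", "n_events", "mean_duration",
                                    "sd_duration")) {
  if (length(metrics_list) < 3L)
    stop_invalid("need at least 3 subjects for group tests")
  long <- do.call(rbind, lapply(seq_along(metrics_list), function(i) {
    st <- metrics_list[[i]]$states
    st$subject <- i
    st
  }))
  states <- unique(long$state)
  out <- do.call(rbind, lapply(metrics, function(m) {
    wide <- stats::reshape(long[, c("subject", "state", m)],
                           direction = "wide", idvar = "subject",
                           timevar = "state")
    vals <- as.matrix(wide[, -1, drop = FALSE])
    colnames(vals) <- sub(paste0("^", m, "\\."), "", colnames(vals))
    complete <- stats::complete.cases(vals)
    n_excluded <- sum(!complete)
    if (n_excluded > 0)
      message(sprintf("%s: %d subject(s) excluded for missing values",
                      m, n_excluded))
    vals <- vals[complete, , drop = FALSE]
    if (nrow(vals) < 3L)
      return(data.frame(metric = m, n_subjects = nrow(vals),
                        n_excluded = n_excluded, F = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p_anova = NA_real_,
                        t_breath_mw = NA_real_, p_breath_mw = NA_real_,
                        t_breath_self = NA_real_, p_breath_self = NA_real_,
                        df_t = NA_real_))
    d <- data.frame(y = as.vector(vals),
                    state = factor(rep(colnames(vals), each = nrow(vals))),
                    subject = factor(rep(seq_len(nrow(vals)),
                                         times = ncol(vals))))
    fit <- stats::aov(y ~ state + Error(subject), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    rownames(tab) <- trimws(rownames(tab))
    Fv <- tab["state", "F value"]
    pv <- tab["state", "Pr(>F)"]
    # identical values across states leave only rounding dust in both strata
    if (is.na(Fv) || tab["state", "Sum Sq"] < 1e-8) { Fv <- 0; pv <- 1 }
    t_mw <- paired_t(vals[, "Breath"], vals[, "MW"])
    t_self <- paired_t(vals[, "Breath"], vals[, "Self"])
    data.frame(metric = m, n_subjects = nrow(vals),
               n_excluded = n_excluded, F = Fv, df1 = tab["state", "Df"],
               df2 = tab["Residuals", "Df"], p_anova = pv,
               t_breath_mw = t_mw$t, p_breath_mw = t_mw$p,
               t_breath_self = t_self$t, p_breath_self = t_self$p,
               df_t = nrow(vals) - 1)
  }))
  rownames(out) <- NULL
  structure(out, class = c("group_metrics_result", "data.frame"))
}

# paired two-sided t robust to a zero-variance difference
paired_t <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) {
    list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
         p = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(tt$statistic), p = unname(tt$p.value))
  }
}
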