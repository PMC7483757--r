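#!/usr/bin/env Rscript
# Step 2 + metric computation: train the full five-state model per subject,
# decode the independent meditation run into Breath/MW/Self, smooth
# singleton decisions, extract mental events (>= 3 consecutive volumes),
# and compute per-subject attention metrics. Only subjects passing the
# Step 1 inclusion rule are decoded (rerun analysis/02 first).

source("analysis/00_cohort.R")

step1 <- read.delim("results/step1_accuracy.tsv")
use <- step1$subject[step1$included]
cat(sprintf("decoding %d included subjects\n", length(use)))

summary_rows <- list()
metrics_list <- list()

for (i in use) {
  s <- cohort_subject(i)
  fit <- cohort_model(s)
  med <- simulate_meditation(s$truth, seed = cohort$subject_seeds[i] + 500L)
  run <- decode_meditation(fit$model, med$ts)
  m <- compute_metrics(run)
  metrics_list[[as.character(i)]] <- m
  dec_occ <- 100 * prop.table(table(factor(run$smoothed_decisions,
                                           meditation_states())))
  true_occ <- 100 * prop.table(table(factor(med$states,
                                            meditation_states())))
  summary_rows[[length(summary_rows) + 1L]] <- data.frame(
    subject = i, n_events = nrow(run$events),
    pct_smoothed = run$pct_smoothed, pct_excluded = run$pct_excluded,
    decoded_breath = dec_occ["Breath"], decoded_mw = dec_occ["MW"],
    decoded_self = dec_occ["Self"], true_breath = true_occ["Breath"],
    true_mw = true_occ["MW"], true_self = true_occ["Self"],
    volume_agreement_pct = 100 * mean(run$smoothed_decisions == med$states))
  if (i == use[1]) {
    write_event_tsv(run, "results/step2_subject_events_example.tsv")
    write_decoded_tsv(run, "results/step2_subject_decoded_example.tsv")
  }
  cat(sprintf("subject %2d: %d events, %.1f%% smoothed, %.1f%% excluded, %.0f%% agreement with hidden states\n",
              i, nrow(run$events), run$pct_smoothed, run$pct_excluded,
              100 * mean(run$smoothed_decisions == med$states)))
}

tab <- do.call(rbind, summary_rows)
rownames(tab) <- NULL
write.table(tab, "results/step2_decoding_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_metrics_tsv(metrics_list, "results/step3_metrics.tsv")
cat(sprintf("\nmean smoothed %.2f%%, mean excluded %.2f%%\n",
            mean(tab$pct_smoothed), mean(tab$pct_excluded)))
cat("wrote results/step2_decoding_summary.tsv, results/step3_metrics.tsv and example TSVs\n")
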