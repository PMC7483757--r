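#!/usr/bin/env Rscript
# Step 1: within-task cross-validation. For every subject, train one-vs-rest
# L2 logistic classifiers (penalty 0.01, 6-s label shift) with
# leave-one-block-out cross-validation; report per-condition accuracy, the
# chi-square inclusion rule, the group t-test vs 20% chance, the pooled
# confusion matrix, and trial-level accuracy-rating correlations.

source("analysis/00_cohort.R")

acc <- matrix(NA_real_, cohort$n_subjects, 5,
              dimnames = list(NULL, ia_conditions()))
included <- logical(cohort$n_subjects)
confusion <- matrix(0L, 5, 5, dimnames = list(ia_conditions(),
                                              ia_conditions()))
rating_trials <- list()

for (i in seq_len(cohort$n_subjects)) {
  s <- cohort_subject(i)
  cv <- crossval_subject(s, penalty = cohort$penalty,
                         lag_seconds = cohort$lag_seconds)
  rep <- evaluate_decisions(cv)
  acc[i, ] <- rep$accuracy
  included[i] <- rep$included
  confusion <- confusion + unclass(rep$confusion)
  rated <- simulate_ratings(s$design, s$truth, coupling = 1, noise_sd = 0.5,
                            seed = cohort$subject_seeds[i] + 900L)
  ta <- trial_accuracies(cv, rated)
  ta$subject <- i
  rating_trials[[i]] <- ta[!is.na(ta$rating), ]
  cat(sprintf("subject %2d: mean accuracy %.1f%%, included = %s\n",
              i, mean(rep$accuracy), rep$included))
}

cat(sprintf("\nincluded %d/%d subjects (>=2 of Breath/MW/Self above chance at p < 0.001)\n",
            sum(included), cohort$n_subjects))
group <- group_accuracy_test(acc)
print(group, digits = 3)

trials <- do.call(rbind, rating_trials)
rc_all <- rating_correlation(trials, scope = "all")
rc_breath <- rating_correlation(trials, scope = "breath")
cat(sprintf("accuracy-rating correlation: mean Z = %.3f (t = %.2f, p = %.3g); breath-only mean Z = %.3f (t = %.2f, p = %.3g)\n",
            rc_all$mean_z, rc_all$t, rc_all$p,
            rc_breath$mean_z, rc_breath$t, rc_breath$p))

write.table(cbind(subject = seq_len(cohort$n_subjects),
                  as.data.frame(acc), included),
            "results/step1_accuracy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(group, "results/step1_group_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(truth = rownames(confusion), confusion),
            "results/step1_confusion.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(all_conditions = rc_all[c("mean_z", "t", "df", "p")],
       breath_only = rc_breath[c("mean_z", "t", "df", "p")]),
  "results/step1_rating_correlation.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/step1_*.tsv and results/step1_rating_correlation.json\n")
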