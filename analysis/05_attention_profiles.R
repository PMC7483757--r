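#!/usr/bin/env Rscript
# Step 3 group analysis: one-way repeated-measures ANOVA over the three
# states per metric, followed by planned paired t-tests of Breath vs MW and
# Breath vs Self. Reads the per-subject metrics written by analysis/04.

source("analysis/00_cohort.R")

long <- read.delim("results/step3_metrics.tsv")
metrics_list <- lapply(split(long, long$subject), function(d) {
  structure(list(states = d[, c("state", "pct_time", "n_events",
                                "mean_duration", "sd_duration")],
                 total_events = sum(d$n_events),
                 pct_excluded = d$pct_excluded[1],
                 denominator = "decodable"),
            class = "attention_metrics")
})
cat(sprintf("group tests over %d subjects\n", length(metrics_list)))

g <- group_tests(metrics_list)
print(g, digits = 3)

state_means <- aggregate(long[, c("pct_time", "n_events", "mean_duration",
                                  "sd_duration")],
                         by = list(state = long$state), FUN = mean,
                         na.rm = TRUE)
print(state_means, digits = 3)

write.table(g, "results/step3_group_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(state_means, "results/step3_state_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/step3_group_tests.tsv, results/step3_state_means.tsv\n")
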