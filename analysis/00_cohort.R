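# Shared cohort configuration for the analysis drivers. Source from the
# repository root. The cohort emulates a single-session study: 16 subjects,
# a six-block internal-attention task, and one 10-min meditation run each.

library(iastates)

cohort <- list(
  n_subjects = 16L,
  n_voxels = 300L,
  snr = 0.3,            # moderate pattern fidelity
  occupancy = c(Breath = 0.5, MW = 0.25, Self = 0.25),
  penalty = 0.01,
  lag_seconds = 6,
  subject_seeds = 101:116,
  design_seed = 1L
)

dir.create("results", showWarnings = FALSE)

cohort_design <- function(i) {
  # each subject gets one of the four stimulus order sets, rotating
  make_task_design(seed = cohort$design_seed, order_set = ((i - 1L) %% 4L) + 1L)
}

cohort_subject <- function(i) {
  simulate_subject(cohort_design(i), n_voxels = cohort$n_voxels,
                   snr = cohort$snr, seed = cohort$subject_seeds[i],
                   occupancy = cohort$occupancy)
}

# full five-state model trained on all six blocks (used for decoding and
# importance maps)
cohort_model <- function(subject) {
  full <- concat_blocks(lapply(subject$blocks, detrend_linear),
                        lapply(subject$labels, shift_labels,
                               lag_seconds = cohort$lag_seconds))
  list(model = train_classifier(full$ts, full$labels,
                                penalty = cohort$penalty),
       ts = full$ts, labels = full$labels)
}
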