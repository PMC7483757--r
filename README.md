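# iastates

Decoding internal-attention brain states from multivoxel fMRI patterns.

During breath-focused meditation the only thing that changes is where
attention is directed — there is no stimulus or behaviour to score. This
package measures that hidden variable with within-subject multivoxel pattern
analysis (MVPA): a classifier first learns each person's neural signatures of
five internal-attention states from a labelled task, then reads out an
independent meditation run second by second, and finally summarizes the
read-out as attention metrics. It is written for cognitive-neuroscience
researchers who want the full pipeline — including a synthetic-data generator
with known ground truth — so every stage can be validated end to end without
scanner data.

## The model

**Step 1 — individual brain patterns.** A six-block internal-attention task
labels volumes with five conditions — attention to the breath, to the feet,
mind wandering (MW), self-referential processing (Self), and ambient sounds —
balanced at 72 s/condition/block (432 volumes per condition, 2,160 in total
at TR = 1 s). After per-block linear detrending and a 6-s label shift for
hemodynamic lag, one binary L2-penalized logistic model is fitted per
condition (one vs. the rest), minimizing

    -Σᵢ [ yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ) ] + λ‖w‖²,   λ = 0.01,

giving five evidence values eᶜ(t) ∈ (0,1) per volume; the argmax is the
categorical decision. Accuracy is estimated by leave-one-block-out
cross-validation (6 folds × 360 decisions = 2,160; 1,800 training volumes
per fold), tested per condition against the 20% chance level (one-sample t,
Cohen's d at the group level; per-subject chi-square of correct/incorrect
counts vs. the 0.2/0.8 split). Subjects with at least 2 of {Breath, MW,
Self} above chance at p < 0.001 are retained for decoding.

**Step 2 — meditation decoding.** The five-state model, trained on all
2,160 volumes, is applied to a 10-min meditation run (600 decodable volumes)
restricted to Breath/MW/Self. Single discordant decisions flanked by two
runs of one common state are relabelled (singleton smoothing), and "mental
events" are maximal runs of ≥ 3 consecutive identical decisions; shorter
runs are excluded.

**Step 3 — attention metrics.** Per state: percentage time engaged, number
of events, mean and SD of event durations; compared across states with a
repeated-measures ANOVA and planned paired t-tests (Breath vs. MW, Breath
vs. Self).

Importance maps (classifier weight × z-scored mean activation per voxel,
thresholded at ±2 SD, pooled into across-subject frequency maps) show which
voxels drive each classification.

## Worked example

```r
library(iastates)

design <- make_task_design(seed = 1)            # 6 blocks, 13 trials each
subject <- simulate_subject(design, n_voxels = 300, snr = 0.3, seed = 101)
cv <- crossval_subject(subject)                 # detrend + 6-s shift + LOBO CV
report <- evaluate_decisions(cv)
report
#> <accuracy_report>
#> Breath   Feet     MW   Self Sounds
#>   53.5   52.1   50.0   50.7   51.4
#> included for meditation decoding: TRUE

full <- concat_blocks(lapply(subject$blocks, detrend_linear),
                      lapply(subject$labels, shift_labels))
model <- train_classifier(full$ts, full$labels) # all 2,160 volumes
med <- simulate_meditation(subject$truth, seed = 601)
round(100 * prop.table(table(med$states)))     # realized hidden occupancy
#> Breath     MW   Self
#>     30     36     34
run <- decode_meditation(model, med$ts)
run
#> <decoded_run> 600 volumes, 65 events; 2.8% smoothed, 35.7% excluded
compute_metrics(run)
#> <attention_metrics> 65 events, 35.7% of volumes excluded
#>    state pct_time n_events mean_duration sd_duration
#> 1 Breath     19.2       20          5.75        3.58
#> 2     MW     18.8       17          6.65        3.79
#> 3   Self     26.3       28          5.64        3.39
```

Cross-validated accuracy sits near 50% per condition (chance 20%) at this
moderate pattern fidelity (snr 0.3). The meditation generator targets an
occupancy of 0.50 Breath / 0.25 MW / 0.25 Self, but a single 600-volume
dwell chain is variable — this run happened to realize 30/36/34 — and the
decoded time shares track the realized sequence (65% of volumes agree),
with the remainder spread by decoder noise and sub-3-volume exclusions.
Averaged over the 16-subject cohort in `analysis/`, decoded percentage time
recovers the breath-dominant profile (31% Breath vs. 17% MW / 20% Self; see
`results/step3_state_means.tsv`).

The `analysis/` directory holds the numbered drivers that run this workflow
over a 16-subject synthetic cohort (`01_simulate_cohort.R` …
`05_attention_profiles.R`, each writing its tables under `results/`).

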