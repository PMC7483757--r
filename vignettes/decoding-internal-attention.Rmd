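---
title: "Decoding internal attention: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding internal attention: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery of `iastates`, the
assumptions behind it, and the choices we made where the design was
genuinely open. It states no empirical result that the package's test suite
and analysis drivers do not themselves compute.

## The measurement problem

Meditation has no overt behaviour: the quantity of interest — where
attention is directed — is internal. The package treats this as a decoding
problem. A labelled internal-attention (IA) task provides training data in
which the subject's attentional state is experimentally controlled; a
classifier learns each subject's multivoxel signatures of five states
(Breath, Feet, MW, Self, Sounds); the trained model is then applied,
across task, to an unlabelled meditation run, and the decoded state
sequence is summarized into attention metrics.

Everything is within subject. No spatial normalization, atlas or
cross-subject alignment enters the decoding: multivoxel patterns are
idiosyncratic, and the group level only ever sees per-subject summary
statistics (accuracies, Fisher-z correlations, metric values) or voxelwise
frequency counts on an already-shared grid.

## Classifier

For each condition $c$ we fit an independent binary logistic model (that
condition vs. the other four) on the labelled volumes, minimizing the
penalized negative log-likelihood

$$
J(w, b) = -\sum_i \left[ y_i \log p_i + (1-y_i)\log(1-p_i) \right]
          + \lambda \lVert w \rVert^2,
\qquad p_i = \sigma(w^\top x_i + b),
$$

with the intercept unpenalized. Two conventions matter here:

* **Penalty convention.** $\lambda$ multiplies the squared weight norm of
  the *summed* (not averaged) likelihood. The default $\lambda = 0.01$ is
  therefore a very weak ridge whose main job is to keep weights finite when
  the classes are linearly separable (common with more voxels than training
  volumes). Users of glmnet should note the mapping
  $\lambda_{\text{glmnet}} = 2\lambda/N$ with `alpha = 0`,
  `standardize = FALSE`; the test suite verifies this equivalence
  numerically.
* **No renormalization.** The five evidence values per volume come from
  independent one-vs-rest models and deliberately do not sum to one. The
  categorical decision is the evidence argmax; restricting the decision to
  a subset (the three meditation-relevant states) simply restricts the
  argmax, without renormalizing.

The fit is Newton/IRLS with step halving, converged when the largest
coefficient update falls below `tol = 1e-6` (our choice; the likelihood is
strictly convex for $\lambda > 0$ so the optimum is unique and the
tolerance only bounds rounding in the last digits). A unit test checks the
fit against direct likelihood maximization with `optim()` on a small
problem.

Numerical edge cases: evidence values are computed from linear scores
clamped to $\pm 30$ before the sigmoid so they remain strictly inside
$(0,1)$ in double precision; decisions are taken on the *unclamped* linear
scores (the sigmoid is monotone, so the argmax is identical) because at
large margins the clamped sigmoid saturates and would manufacture ties.
Genuine ties are broken toward the earliest condition in the declared order
(Breath, Feet, MW, Self, Sounds), with a warning — deterministic and
auditable.

## Preprocessing

Only two analysis-side operations are modelled; slice-timing and motion
correction are upstream responsibilities for real data and unnecessary for
synthetic data.

* **Per-block linear detrending.** Blocks are separate scanner runs, so the
  line is fitted and removed within block. Detrending is idempotent and
  invariant to any added linear trend, which the tests check directly.
* **Confound regression** projects each voxel onto the orthogonal
  complement of an intercept plus user-supplied confound columns (e.g.
  motion parameters). Rank-deficient confounds produce a warning and a
  projection onto the column span.
* **Hemodynamic label shift.** Neural events reach the BOLD signal late;
  condition labels are moved 6 s later (a whole-volume shift at TR = 1 s),
  within block only. Volumes that lose their label at block edges become
  unlabelled and are excluded from training and from accuracy denominators.
  Lags that are not a multiple of the TR are rounded to the nearest volume
  with a warning.

## Cross-validation and inference

Folds are blocks: train on five, test on the held-out sixth, rotate. With
the default design this yields 2,160 decisions from folds of 1,800 training
volumes, and every labelled volume is tested exactly once by a model that
never saw its block.

Per-condition accuracy is tested at the subject level with a chi-square
goodness-of-fit of correct/incorrect counts against the chance split
(0.2/0.8 of the 432 decisions, i.e. expected counts 86.4/345.6 — we keep
the exact expectation rather than rounding to integers). A subject is
retained for meditation decoding when at least two of Breath, MW and Self
are *above* chance at $p < 0.001$; the direction guard matters because a
two-sided chi-square would also fire on significantly below-chance
conditions. Group-level accuracy per condition uses a one-sample two-sided
t-test against 20% with Cohen's $d$; t and d are scale-invariant, so
percent and proportion inputs agree.

Trial-level accuracy–rating correlations use Pearson's $r$ within subject
over rated trials (ratings exist only in the last half of the blocks and
never for MW trials, where subjects are instructed not to attend), Fisher
$z = \operatorname{atanh}(r)$, and a one-sample t-test of the group mean
$z$ against zero. Subjects with fewer than three rated trials in scope or
zero variance in either variable have undefined $r$ and are dropped with a
warning.

## Meditation decoding and event segmentation

The full five-state model (trained on all 2,160 volumes) decodes each of
the 600 decodable meditation volumes among Breath/MW/Self. Two data
reductions then separate sustained states from flicker:

* **Singleton smoothing.** A run of length 1 flanked by two runs of one
  common state is relabelled to that state. "Event-like" flank is
  interpreted as length ≥ 2 (`min_flank = 2`), so a merged run has length
  ≥ 5 and is necessarily an event; stricter (≥ 3) or looser (≥ 1) readings
  are configuration options. Smoothing is a single left-to-right pass over
  the original run structure; newly merged runs are not re-scanned (an
  iterative mode exists, off by default). Percent smoothed is reported.
* **Event extraction.** Maximal runs of ≥ 3 identical decisions
  (`min_event_length = 3`, i.e. 3 s at TR = 1 s; 2 and 4 are exposed for
  sensitivity analyses) become mental events; shorter runs are excluded and
  their volume share reported. Events never span the boundary between the
  two meditation blocks — states cannot be observed across a scan gap — and
  smoothing respects the same boundary.

Both operations are validated against a brute-force position-by-position
reference on 10,000 random sequences.

## Attention metrics and group contrasts

Per state: percentage time engaged, event count, mean and sample SD
(n − 1) of event durations. The percentage-time denominator is all 600
decodable volumes, so state percentages plus the excluded percentage sum
to exactly 100 (an identity the tests assert); normalizing by event time
only is available via `denominator = "events"`. States with a single event
report a missing SD rather than 0.

Group contrasts use a one-way repeated-measures ANOVA (subject as the error
stratum; df (2, 2(n−1))) per metric, matched to the planned paired
two-sided t-tests of Breath − MW and Breath − Self. Subjects missing a
metric value in any state are dropped from that metric's tests with the
count reported. Degenerate inputs (identical values everywhere) are mapped
to F = 0, t = 0, p = 1 rather than NaN.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage is testable against known ground
truth, with the task structure as its template:

* **Design:** six blocks of 13 trials (3 × Breath/Feet/Sounds, 2 ×
  MW/Self), 20 s baseline at both block ends, 2 s unlabelled instruction
  before each trial, 72 s labelled per condition per block. Short-condition
  durations are even values in 16–32 s, each used exactly twice per
  condition across the experiment, partitioned into per-block triples
  summing to 72 s by a seeded backtracking search. MW/Self durations are
  even values in 22–50 s drawn as per-block pairs summing to 72 s with
  distinct short members, covering most of the range while keeping the
  432 s experiment-wide total exact. The original four fixed stimulus
  orders are not published, so four candidate orders are derived from the
  seed and `order_set` picks one.
* **Signal:** each condition's pattern loads on a random ~10% voxel subset
  with unit-RMS values scaled by `snr` (pattern amplitude over noise SD;
  `snr = 0` carries no condition signal, and the full pipeline then sits at
  the 20% chance level, which the acceptance suite checks). The
  hemodynamic effect is a pure 6-s onset delay mirroring the analysis-side
  label shift; HRF convolution is a possible extension, not the default.
  Per-trial attention is modulated by a log-normal fidelity multiplier
  (`attention_sd = 0.3`, unit mean) that also drives the rating generator.
* **Noise:** AR(1) Gaussian noise with $\phi = 0.3$ and unit marginal
  variance, plus a per-voxel linear drift whose block-amplitude SD is 1 —
  a minimal, tunable fMRI-like noise model.
* **Meditation:** a hidden semi-Markov chain over Breath/MW/Self with
  geometric dwell above a 3-volume minimum, mean dwell proportional to the
  requested occupancy (18/9/9 volumes at the default 0.5/0.25/0.25) and
  uniform switching, emitted in two blocks (40%/60%, emulating a 4 + 6 min
  session) with 8 unlabelled instruction volumes prepended per block so
  that decodable volumes equal 600 exactly.
* **Ratings:** a latent score (coupling × trial fidelity + Gaussian noise)
  discretized monotonically into within-subject quartiles 1–4, so the full
  response range is used and `coupling = 0` yields independence.

Not emulated: spatial smoothness and voxel correlation structure,
physiological (cardiac/respiratory) confounds, susceptibility artifacts,
motion, HRF shape variability. Passing tests therefore establish the
*logic and calibration* of the pipeline — balanced designs, unbiased chance
level, monotone accuracy in SNR, exact run-length arithmetic, occupancy
recovery — not performance on real scanner data, where noise is richer and
accuracies will differ.

## Importance maps

Importance is weight × z-scored activation. Two z-scoring axes are
defensible; we default to z-scoring each voxel's time course across volumes
and averaging within the condition (so activation is in within-voxel SD
units), with `z_axis = "voxels"` available to z-score the raw condition
means across voxels instead. Voxels where weight and activation agree in
sign are classed positive/negative; mixed-sign voxels are classed `none`
and never retained, since only the two concordant classes are meaningfully
"important". Thresholding z-scores the importance values across voxels and
retains $|z| \ge 2$ (for Gaussian importances, ≈ 4.55% of voxels, which the
tests verify by simulation). Frequency maps count retaining subjects per
voxel, pooling signs by default. Mask-overlap percentages operate on any
user-supplied binary mask on the same grid; no atlas is bundled, and group
maps on real data require upstream registration to a shared grid.

## Problem sizes used in validation

The test and acceptance suites run the full pipeline at sizes chosen to
make their statistical targets sharp while remaining desk-scale: the null
calibration uses 500-voxel subjects over 5 seeds (tolerance ±2 percentage
points around 20%); SNR monotonicity uses 200 voxels × 3 seeds over
snr ∈ {0, 0.5, 1, 2}; occupancy recovery uses 200-voxel subjects at snr = 2
over 5 seeds (tolerance 5 percentage points against the realized hidden
sequence); the run-length oracle uses 10,000 random sequences. Group-level
power and ANOVA-calibration checks run on metrics computed from
ground-truth dwell chains (20 cohorts × 14 subjects, and 120 cohorts × 8
subjects respectively), since decoding fidelity at snr ≥ 2 is established
separately. The `analysis/` drivers use a 16-subject cohort at 300 voxels
and snr = 0.3, a fidelity chosen to exercise the inclusion rule and yield
mid-range accuracies rather than ceiling performance.

## Known limitations

* The synthetic noise model omits spatial correlation, so whole-brain
  voxel counts behave like independent features; real-data accuracy will
  not scale the same way with voxel count.
* The decoder assumes the meditation run is preprocessed identically to
  training data and sits on the same voxel grid; no alignment is performed.
* The repeated-measures ANOVA assumes sphericity; with three levels and
  the package's planned paired follow-ups this is mild, and no correction
  is applied.
* Percentage-time metrics are compositional (they sum with the excluded
  share to 100), so state-wise tests are not independent; the planned
  contrasts are the primary inference.
* `simulate_meditation`'s occupancy is a long-run target: single
  600-volume chains realize it with substantial variance, which is real
  dwell-time variability, not generator error.
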