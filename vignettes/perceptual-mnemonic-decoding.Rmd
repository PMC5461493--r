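---
title: "Perceptual and mnemonic direction coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual and mnemonic direction coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of **pmdecode**: the
experimental structure it assumes, the per-neuron and population-level
estimators, the synthetic-data generator used to validate them, and the
numerical and design choices a careful user should know about. Code chunks
are shown but not evaluated here; the same computations run, with asserted
outcomes, in the package's test suite.

## Experimental structure and data model

The design is a two-task delayed match-to-sample experiment. On every trial
a random-dot sample moves in one of four directions spaced 90° apart; after
1,000 ms the sample either disappears (memory task — the direction must be
held in working memory) or stays on screen (perceptual task), and a delay of
1,200–2,000 ms follows before the test stimuli. Trials of the two tasks are
randomly interleaved, giving eight task × direction conditions.

A `pm_dataset` stores, for each neuron, a trials × bins matrix of firing
rates covering the sample plus the *first 1,200 ms* of the delay (the delay
length varies across trials, so only the guaranteed portion is analysed),
binned at 40 ms with bin 0 at sample onset and half-open bins `[t, t +
bin_ms)`. Delay onset is defined as 1,000 ms after sample onset in both
tasks — in the perceptual task the sample simply remains visible during
"its" delay. All delay-period statistics use the **240–1,200 ms** window
after delay onset: the first 240 ms are excluded so that residual sensory
transients from the sample do not masquerade as delay coding. Windows must
align to whole bins; misaligned windows are rejected rather than silently
truncated.

Analyses operate on binned mean rates throughout; spike times are out of
scope.

## Per-neuron statistics

**Direction discriminability.** For one neuron and task, the delay-mean
rates of every pair of direction conditions are compared with the area
under the ROC curve, computed through the Mann–Whitney identity (ties count
one half). Values below 0.5 are rectified (`max(v, 1 − v)`) so
discriminability is direction-of-effect agnostic, and the maximum over the
six direction pairs is the neuron's discriminability; the direction with
the highest mean rate is its preferred direction (exact ties go to the
lowest angle, a deterministic rule that matters only for degenerate data).

**Permutation significance.** The full procedure (including the max over
pairs, which biases the statistic above 0.5 even for untuned neurons) is
repeated after shuffling direction labels, 500 times by default; the real
value is significant if it reaches or exceeds the 99th percentile of the
surrogates. P-values use the add-one estimator `(1 + k)/(1 + n)` and can
therefore never be zero. Because 500 surrogates bound p at 1/501, a
family-wise correction across neurons is not resolvable at this resolution;
the per-neuron percentile rule is the default, and an optional
Benjamini–Hochberg FDR flag (`fdr = TRUE` in `classify_neurons()`) is
provided for users who want a stricter criterion.

**Functional classes.** A neuron is **PM** if significant in both tasks
(the two tests use disjoint trials, so the classification is not coupled by
construction), **P**/**M** if significant in one, **X** otherwise. The
significance threshold is inclusive ("reached or exceeded").

**PM excess.** To test whether dual-coding neurons are more frequent than
independence would predict, the perceptual-significance flags and the
mnemonic-significance flags are independently reshuffled across the
*entire* classified population, and the real percentage of doubly
significant neurons is ranked among 10,000 surrogate percentages.
Restricting the shuffle pool to the significant neurons themselves would
make an excess mathematically undetectable whenever most significant
neurons are PM (the surrogate overlap is then forced to match or exceed the
real one), so the whole-population pool is the only coherent reading.

**Choice probability.** For neurons selective in a task, CP is the auROC
between delay rates of correct versus error trials whose sample moved in
the neuron's preferred direction, oriented so CP > 0.5 means higher rates
on correct trials. Neurons with fewer than five correct or five error
preferred-direction trials are excluded (`NA`, not an error). CP reuses the
same 240–1,200 ms window as discriminability. Group tests are one-tailed
Wilcoxon signed-rank tests (per-task mean vs 0.5; within-neuron memory −
perceptual difference vs 0).

## Population decoding

**Pseudopopulation.** Sessions are pooled after rigidly rotating each
direction set onto 0/90/180/270. For each neuron, 30 correct trials per
condition are drawn and their within-condition order shuffled independently
per neuron, randomly assigning trial "simultaneity" — this deliberately
destroys trial-by-trial noise correlations, which non-simultaneous
recordings cannot estimate anyway. Neuron bootstraps may duplicate a
neuron; each copy draws its own trials, so duplicates are not redundant.

**Classifier.** Diagonal linear discriminant analysis: per-class feature
means, a single pooled within-class diagonal covariance, uniform priors
(training is balanced by construction), prediction by the smallest
variance-scaled squared distance, ties to the lowest class index.
Degenerate features get a variance floor of 10⁻⁶ of the mean pooled
variance.

**Cross-validation and preprocessing.** Eight-way condition decoding uses
leave-one-out over the 240 pseudotrials; inside *every* fold, per-neuron
z-scoring parameters and an 8-level one-way ANOVA feature gate (α = 0.01,
configurable — the gate's level is a documented divergence risk since no
canonical value exists) are fitted on the 239 training rows only. If no
neuron passes the gate — which happens regularly under label-shuffled nulls
— all neurons are retained for that fold so the classifier stays defined;
this fallback does not bias the null (chance-level features in, chance-level
predictions out). The leave-one-out engine re-fits the fold models through
rank-one downdates of the class sums, which keeps the full protocol at
O(trials × neurons) per decode.

**Summaries.** Task accuracy is the percentage of trials decoded into a
condition of the same task; direction accuracy is computed separately
within task-correct and task-error trials, per true task, with empty
partitions reported as `NA` rather than 0. A balanced 25/5
train/test variant of the protocol exists in the underlying fold machinery
only as leave-one-out; the 2-fold cross-task analysis (below) covers the
balanced-split case.

**Uncertainty and chance.** Accuracy variability comes from 100 bootstraps
over neurons; two accuracies are compared by pooling their bootstrap values,
reassigning them at random 1,000 times, and ranking the real mean difference
(one-sided, add-one). Chance comes from rerunning the *entire* pipeline —
including fold-wise preprocessing — after shuffling condition labels, 1,000
times at full scale.

**Cross-task decoding.** Within each task the 120 direction trials are
split 60/60 (stratified by direction); a classifier trained on one fold of
the training task is tested on the complementary fold of the testing task,
so train and test rows never overlap even when the tasks coincide. The
ANOVA gate is re-fitted on each training fold with the four direction
conditions of the training task.

**Class removal and regions.** Removing a functional class is always
compared against a size-matched control drawn from the full population
without replacement, so the comparison isolates *which* neurons were
removed from *how many*. The same logic downsamples "outside" neurons to
the "inside" count in the regional analysis.

## Cross-temporal generalization and stability

The direction classifier is trained on the average rates in one time window
and tested in the same or any other window (same pseudotrial mapping
everywhere, leave-one-out folds shared across windows). Each window's
features are z-scored with that window's training-fold statistics — the
only convention that puts train- and test-window features on a common scale
when the overall rate level drifts over the trial.

A delay testing window counts as **stable** for a given training window if
its accuracy is (a) above chance — add-one p against the label-shuffle null
of that cell below α = 0.01 — and (b) not significantly below the
same-window accuracy (one-sided bootstrap comparison at the same α). The
stability percentage is the fraction of stable delay testing windows,
convertible to milliseconds of the analysed delay span. Two consequences of
the add-one estimator are worth noting: the above-chance gate needs at
least 100 null maps (p floor `1/(n+1)`), which is why `n_null` defaults to
100, and the bootstrap comparison needs enough permutations for p to fall
below α.

## The synthetic-data generator

For neuron *i*, task *τ*, direction *θ* and bin *t*, the expected rate is

λ = max(0, b + Δ·[τ = memory] + g_τ · cos(θ − φ_τ) · m(t, τ) + β·u),

with Poisson bin counts (mean λ·bin/1000) stored as rates. The components
emulate, one per analysis stage:

* **cosine tuning** with task-wise gains g_P, g_M and preferred directions
  φ_P, φ_M — cosine is the minimal smooth model on a 4-point grid that
  produces the feature-proximity structure (orthogonal directions
  intermediate between preferred and anti-preferred); with only four
  directions no richer tuning function is identifiable anyway;
* **m(t, τ)**, a smooth positive temporal modulation (Gaussian-kernel
  filtered noise, mean 1, correlation time `tau_ms` = 300 ms, sd `mod_sd` =
  1.2, floored at 0.05, fixed across trials) — dynamic delay codes;
* **Δ**, a memory-task rate offset, and independently drawn φ_M —
  task-distinguishable codes;
* **β·u**, a per-trial latent u ~ N(0,1) shared between all neurons' rates
  and the behavioural outcome (correct with probability
  `plogis(qlogis(p_correct) + u)`) — choice probability above 0.5 when
  β > 0;
* **positions**: strongly tuned neurons drawn from a Gaussian cluster when
  configured, others uniform — anatomical topography.

Parameter defaults (baseline 10 spikes/s, gain 3 spikes/s, 30 trials per
condition, behavioural accuracy 85%) were chosen once from the signal
arithmetic of the analyses: gain 3 on baseline 10 yields a preferred-vs-anti
d′ ≈ 1.9 over the 960-ms delay window, comfortably above the ≈0.72
permutation threshold for 30 trials/direction, so classification recovery is
well powered. Two fixtures deviate deliberately: `weak_cosine` (gain 1)
keeps population direction decoding imperfect so that decoding *errors*
exist for the feature-proximity analysis, and `dynamic_memory` (gain 6)
gives single 200-ms windows enough signal that the *stable* task's
cross-temporal map has power, letting the dynamic memory code's instability
show against it. Both choices come from the same d′ arithmetic, not from
iterating on test outcomes.

Because the decoder uses correct trials only and behavioural accuracy is
85%, fixtures destined for decoding are generated with 50 trials per
condition so that at least 30 correct trials per condition survive with
high probability; per-neuron fixtures keep the default 30.

What the generator does **not** emulate: trial-by-trial noise correlations
between neurons (the pseudopopulation construction destroys them anyway),
overdispersed or bursty spiking (Poisson only), eye movements, stimulus
adaptation, non-cosine tuning, and session-level nonstationarities. Passing
tests therefore certify the *estimators and protocols*, not the biological
fidelity of any particular parameter value.

## Numerical choices and degenerate inputs

* add-one permutation p-values everywhere (`(1 + k)/(1 + n)`); p = 0 is
  impossible except in the clustering test, which follows the
  fraction-of-surrogates-below convention of its field and is reported as
  such;
* preferred-direction ties → lowest angle; classifier ties → lowest class
  index; both deterministic;
* variance floors: z-scoring uses sd = 1 for zero-variance neurons (their
  z-scores are then 0 and carry no information); pooled LDA variances are
  floored at 10⁻⁶ of their mean;
* proximity t-test with (numerically) constant differences returns p = 0 or
  1 by the sign instead of erroring;
* zero preferred-direction rates exclude a neuron from tuning-profile
  normalization with a warning; ratios with non-finite values are dropped
  from the profile ratio average;
* every stochastic step takes an explicit seed; stage seeds are derived
  from a master seed by a fixed integer map, so `pm_run_all()` reports are
  bit-reproducible.

## Scale of the shipped validation

The test suite exercises the full-scale protocol shapes (500 shuffles, 30
pseudotrials per condition, leave-one-out over 240 trials) but reduces
repetition counts where only calibration, not precision, is at stake:
decoding nulls use 200 label shuffles, cross-temporal runs use 200-ms
windows with 12 bootstrap and 100 null maps, and fixtures hold 40–60
neurons. These sizes are the package's chosen desk-scale study conditions;
all counts are arguments, so full-scale runs (40-ms windows, 100
bootstraps, 1,000 shuffles) need only larger values.

## Known limitations

* Eligibility for the pseudopopulation is evaluated on the shared trial
  table; per-neuron trial subsets (neurons recorded for only part of a
  session) are not modelled by the storage format.
* The multiple-comparison treatment of the 500-shuffle test is the
  per-neuron percentile rule by default (see above); users comparing
  class proportions across datasets should fix one convention.
* Choice probability pools all error types; error-mode-specific CP is not
  implemented.
* The cross-temporal stability statistic inherits the discreteness of its
  add-one p-values; with few bootstrap maps the stable/unstable boundary is
  coarse.
* Support-vector-machine re-checks of the decoding results are not
  included.
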