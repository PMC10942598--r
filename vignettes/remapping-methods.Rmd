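---
title: "Methods: cue-conditional remapping statistics for the Tree-Maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cue-conditional remapping statistics for the Tree-Maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazeremap)
```

This vignette documents the statistical methods implemented in
`mazeremap` and the reasoning behind the non-obvious design choices. It
is written for a reader who wants to audit or extend the methods, not as
a usage tour; the README covers the worked end-to-end example.

## 1. Task and linearization

The Tree-Maze is a 39-zone environment: a home well, a stem leading to a
decision point, and two mirrored branches whose four goal wells terminate
the outbound run. Each trial begins with a left or right cue (LC / RC) at
the home well; the correct response is to turn toward the cued side at
the intersection and run to a goal well on that branch.

Because the two branches are geometrically mirrored, analyses that
compare left and right runs use a **linearized position** from 1 to 21:
positions 1–11 cover the home well, stem, and decision point (shared by
all trials), 12–16 the branch approach, 17 the branch intersection,
18–20 the arm, and 21 the goal well. Mirrored left/right zones map to
the same linear position, so a trial's trajectory is a monotone sweep
through 1–21 regardless of side. `treemaze_zones()` exposes the zone
table, adjacency, and the `linear_pos` mapping; `assign_zones()` turns a
tracking trajectory into a per-sample zone sequence.

## 2. Trial parsing and rate maps

`parse_trials()` reconstructs trials from the event log: cue onset,
outbound window (home departure to goal arrival), decision side,
correctness (RC is rewarded at the right-branch wells, LC at the
left-branch wells), and inbound window. Trials with no cue or with a
change of mind at the intersection are retained in the table but marked
`excluded` with a machine-readable `reason`; downstream functions skip
them without special-casing.

`trial_zone_rates()` computes a trials × 39 matrix of firing rates:
spikes assigned to the zone of the nearest earlier tracking sample,
divided by per-trial zone occupancy time. Zones a trial never visited
are `NA`, never zero — a zero would claim evidence of silence the data
cannot support, and Kendall correlations downstream must see those cells
as missing.

## 3. The remapping score

The central statistic asks: are a unit's rate maps under two cue
conditions *less similar* than maps drawn from a condition split that
carries no cue information?

For each of `n_boot` (default 100) paired bootstrap draws:

1. `balanced_resample()` draws trials per condition level, balanced
   within each level over a nuisance factor (for the cue condition,
   equal numbers of correct and incorrect trials per level; the draw
   count per cell is the minority-cell count `m`). This prevents
   reward-outcome composition from masquerading as cue coding.
2. `condition_maps()` averages the drawn trials' zone rates into one map
   per level, propagating `NA` masking.
3. `kendall_tau()` computes the tau-b rank correlation between the two
   maps over their jointly non-missing zones, tau-b because zone rates
   tie often (silent zones, low counts).
4. tau is mapped to a Pearson-scale correlation by the Greiner relation
   `r = sin(pi * tau / 2)` (`tau_to_z()`), Fisher-transformed
   `z = atanh(r)`, and the test condition's z is compared with the
   matched null draw's z via the two-sample Fisher statistic
   `z_delta(z1, n1, z2, n2) = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`,
   with `n` the number of jointly observed zones in that draw.

The score `zbar` is the mean of the paired `z_delta` values. Negative
values mean the cue split decorrelates the maps more than the null
split: remapping.

### 3.1 The parity null and noise matching

The null condition is **trial parity** (odd vs even trial index),
balanced over cue — a split orthogonal to everything the task
manipulates. A subtlety makes the naive version badly biased: if the
null draws use more trials per map than the test draws, null maps are
less noisy, null correlations are higher, and every unit looks like it
remaps. With per-trial map noise variance roughly
`sigma^2 * (1/m + 1/pool)` (m trials drawn from a pool), the test and
null must match both factors. `balanced_resample(..., match_noise =
rs_test)` therefore forces each null draw to use the test plan's
per-level draw count and subsamples the null pool to the harmonic-mean
pool size of the test cells. On no-remapping units this moved the mean
score from −1.44 (naive) to +0.01 (matched).

### 3.2 Calibration and the dispersion caveat

The mean of `zbar` over no-remapping units is well calibrated near 0.
Its **dispersion is not standard normal**: averaging `z_delta` over 100
bootstrap draws removes most of the resampling variance that the Fisher
denominator `sqrt(1/(n1-3) + 1/(n2-3))` prices in, so the across-unit
standard deviation of `zbar` is ≈ 0.35, not 1. Consequently
`|zbar| > 1.96` has a false-positive rate near 0, far below the nominal
5% — a two-sided z-test on `zbar` is conservative, not anti-conservative.
If calibrated per-unit p-values are needed, the empirical across-unit
null distribution (or the single-draw `z_delta` values in the returned
object) should be used instead of the normal reference. The package
reports this honestly rather than rescaling `zbar`, because the score's
*ordering* and population *mean* are the quantities the downstream
analyses consume.

### 3.3 Structured exclusions

When any balancing cell falls below `min_per_cell` (default 5) trials,
`balanced_resample()` returns an exclusion object rather than erroring
or silently drawing unbalanced samples, and `remap_score()` propagates
it (`excluded = TRUE`, `zbar = NA`). Population summaries can then count
exclusions explicitly.

## 4. Synthetic sessions

`simulate_treemaze()` generates an event log, tracking, and
inhomogeneous-Poisson spike trains from per-unit tuning
(`unit_tuning()` / `random_unit_tuning()`):

* `zone_gains` — the base rate map (log-normal across zones by default).
* Rate remapping — a cue gain `g_C` applied multiplicatively on RC
  trials, weighted per zone by `gain_weights` so the remap is
  heterogeneous across the map (a uniform gain would leave ranks, and
  hence tau, untouched).
* Global remapping — an independent zone permutation of the map per cue
  condition (`global_perm`).
* Additive cue coding — `a_C` Hz added on RC trials. This exists
  separately from `g_C` because a multiplicative gain lies inside the
  *interactive* encoder class below; an additive offset is the generator
  whose best matched-basis model is the additive one, which is what an
  identifiability test needs.
* Error coupling — `g_E` scales the remap strength on error trials,
  letting session-level remapping covary with behavioral performance.

## 5. Encoding models on a matched basis

`fit_encoder()` fits per-unit linearized-position encoders on 20 ms
bins with trial-blocked, condition-balanced cross-validation folds:

* `Z0` — one-hot current zone.
* `Z+lag` — zone plus harmonically weighted look-ahead (weight `1/l` at
  lag `l` up to `lag_horizon`), capturing prospective coding.
* `Z+C` — `Z+lag` plus two cue-indicator columns (additive cue shift).
* `ZxC` — the `Z+lag` basis duplicated per cue condition (cue-specific
  maps).

The three non-trivial models share the `Z+lag` backbone so comparisons
isolate *how* cue enters, not how position is represented.
`compare_encoders()` reduces per-fold R² differences to a Mann-Whitney
`UZ` per unit; with 5 folds the statistic is bounded by ±2.611, so it is
a direction-and-consistency summary, not a significance test. The
designed behavior: an additive-offset generator is won by `Z+C`, a
multiplicative/global generator by `ZxC`, because the multiplicative map
change is expressible only with cue-specific coefficients.

## 6. Decoders and the decision statistic

`fit_position_decoder()` is a ridge-regularized multinomial decoder over
the 39 zones (posterior rows normalized; errors are centroid distances,
also summarized per linear position). `fit_decision_decoder()` decodes
the upcoming left/right decision per zone sample, aggregates per trial
into linear-position profiles (`lin_p`), balanced accuracies
(`lin_bac`), and a cumulative integrated log-odds along the
linearization (`clip_logit()` clips at 1e-6 to keep logits finite).
Before the intersection (positions 1–11) a side decode can only reflect
anticipatory coding; after it (12–20) trajectory differences make the
decode near-perfect — this pre/post contrast is the designed readout.

## 7. Session-to-behavior correlation

`behavior_correlation()` relates per-session remapping scores to
performance `p_se` with Kendall's tau plus a linear mixed-effects model
`p_se ~ score + (1 | subject)` and a likelihood-ratio test (OLS fallback
with a warning when only one subject is present). The random intercept
only has power when each subject spans a range of performances; a design
in which subjects occupy disjoint performance bands confounds subject
with performance and the intercepts absorb the effect. The analysis
drivers interleave subjects across the performance grid for this reason.

## 8. Across-session unit matching

`simulate_waveform_sets()` generates per-unit spike-waveform clouds
(128 samples) across sessions. Two generator details matter:

* Between-session drift is an *additive* perturbation with a fixed
  scale (plus a small multiplicative gain term), independent of the
  between-unit `separation` parameter — otherwise increasing separation
  would also inflate same-unit drift and matching accuracy would
  *decrease* with separation, which inverts the physics the benchmark is
  supposed to probe.
* Per-spike amplitude jitter (`amp_jitter`) spreads each cloud along its
  template axis proportionally to template norm, so multiplicative gain
  drift stays a fixed fraction of cloud width at every separation.

`match_units()` embeds each cloud in 2-D (`embed_waveforms()`, seeded
PCA by default; kernel PCA via `method = "kpca"` — the downstream
metrics are embedding-agnostic by design), fits robust Gaussians
(`fit_cluster_gaussian()`, MCD covariance so a few percent of outlier
spikes cannot move the fit), and scores candidate pairs (same tetrode
and depth only) with three metrics: a symmetric misclassification-based
distance `d` in [0, 1], squared Hellinger `H2`, and symmetrized KL.
Pairs below the `d` threshold enter a greedy one-to-one assignment.
The closed forms are tested against Monte-Carlo oracles:
`KL = 0.5` at unit-covariance mean offset (1, 0), and
`H2 = 1 - exp(-0.5) ≈ 0.3935` at offset (2, 0).

## 9. Open-field functional typing

`fit_of_encoder()` fits per-unit models for speed, head direction, and
position on 20 ms samples with 20 s blocked folds (blocking, not random
splits, because rate autocorrelation otherwise leaks across folds). Each
variable is one-hot binned and reduced by PCA to 95% variance; the
position design is built sparsely (`Matrix`) because ~700 position bins
over a long session would not fit densely in memory.

`fit_aggregate_model()` regresses each unit's rate on the three models'
predicted rates. The exported coefficients are **contributions** —
slope × training-set SD of that model's prediction — not raw slopes.
Every single-variable prediction carries the unit's mean rate, so raw
slopes are all near 1 regardless of what the unit codes; a variable the
unit ignores yields a near-flat prediction and hence a near-zero
contribution, which is the quantity that separates functional types.
`cluster_functional_types()` standardizes the contributions, embeds
them (seeded PCA), and k-means-partitions them; `of_tm_transfer()`
carries the cluster labels onto matched Tree-Maze units with bootstrap
CIs per cluster.

`of_tuning_metrics()` includes a head-direction score whose expected
value under von Mises tuning with concentration kappa is the Bessel
ratio `I1(kappa) / I0(kappa)` — an analytic anchor used throughout the
tests.

## 10. Defaults

| Default | Value | Rationale |
|---|---|---|
| `n_boot` | 100 | bootstrap-mean SE well below across-unit spread |
| `min_per_cell` | 5 | below this, balanced draws are mostly duplicates |
| time bin | 20 ms | tracking rate (50 Hz); one sample per bin |
| `lag_horizon` | 3 | harmonic weights beyond 1/3 are negligible |
| decoder `lambda` | 0.01 | mild ridge; zones are near-orthogonal |
| OF fold block | 20 s | longer than rate autocorrelation in the generator |
| match `threshold` | 0.5 | midpoint of `d`'s range; assignment is greedy past it |
| `amp_jitter` | 0.05 | keeps gain drift a fixed fraction of cloud width |
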