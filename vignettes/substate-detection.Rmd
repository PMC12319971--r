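---
title: "Detecting dynamic brain-activity substates in paired pharmacological fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dynamic brain-activity substates in paired pharmacological fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substates)
```

## The analysis in one paragraph

A fast-acting psychedelic such as intravenous DMT alters whole-brain
activity within seconds and washes out within roughly twenty minutes, all
inside a single resting-state fMRI scan. Rather than asking how node-to-node
connectivity changes on average, this package asks *when* the brain revisits
the same spatial activity configuration. For each participant and condition
(drug vs. placebo) it computes a T×T matrix whose (i, j) entry is the
Pearson correlation, across the 112 parcels, between the spatial activity
patterns at volumes i and j. Averaging these matrices within condition and
subtracting placebo from drug yields a subtraction matrix in which positive
blocks mark stretches of time whose brain activity is mutually similar
*specifically under the drug*. Community detection on that thresholded
matrix groups volumes into temporal **substates**; occupancy statistics
before vs. after the injection, a χ² separability criterion, GLM β-maps,
EKG-derived heart rate, and PLS regression against post-session experience
ratings then characterize what each substate is and what it feels like.

## Pipeline and parameters

The stages, each an exported function, are:

1. `time_similarity_matrix()` — spatial Pearson correlation between all
   volume pairs. The correlation is across nodes (spatial), never across
   time; cortical and subcortical parcels enter as one unweighted vector.
   Volumes are 1-based; with the default timing (28 min, TR 2 s, injection
   at the end of minute 8) volume 240 is the last pre-injection volume.
2. `group_mean_matrix()` and `subtraction_matrix()` — element-wise mean
   within condition and drug-minus-placebo difference, diagonal forced to 0.
3. `threshold_matrix()` — keeps entries ≥ r at their value (weighted, not
   binarized; the graph community detection literature's default). Only
   positive differences are kept: the target is drug-specific temporal
   similarity, and absolute-value thresholding (available via
   `use_absolute = TRUE`) would instead recover placebo-specific structure.
4. `louvain_communities()` — greedy modularity maximization on the dense
   modularity matrix with resolution γ = 1, restarted `n_restarts = 100`
   times with random node orders (all randomness flows from the seed), best
   quality Q kept. Negative weights, relevant for the unthresholded control
   path, are handled by the signed-modularity variants: the *symmetric*
   treatment weights positive and negative null models equally
   (B⁺/v⁺ − B⁻/v⁻); the *asymmetric* treatment down-weights the negative
   part by the total weight (B⁺/v⁺ − B⁻/(v⁺+v⁻)). After positive
   thresholding both coincide. Volumes with zero graph weight cannot be
   placed and become reported singletons.
5. `occupancy()`, `separability_chi2()`, `retained_substates()` — per-state
   occupancy fractions of the pre- and post-injection periods, their minute
   equivalents, the omnibus k×2 Pearson χ² (no continuity correction), and
   per-state 2×2 χ² tests. A state is retained when its per-state p < 0.05
   *and* it occupies ≥ 10% of one period. Whether the separability index
   should be read as the omnibus k×2 statistic or as the sum of per-state
   2×2 statistics is genuinely ambiguous; the omnibus table reading is the
   default and the alternative is exposed via `omnibus = "sum_per_state"`.
6. `threshold_sweep()` — repeats 3–5 over r = 0.20, 0.21, …, 0.30 and
   selects the threshold maximizing the number of retained substates. The
   tie-break (larger omnibus χ², then the smaller threshold) is this
   package's deterministic choice; only the winning rule, not the
   tie-break, is prescribed by the method.
7. `kmeans_control()` — k-means on the rows of the subtraction matrix
   (default k = 3, 10 000 iterations, best of 10 replicates by
   within-cluster sum of squares), a non-graph control for the partition.
8. `beta_maps_glm()` / `state_mean_zmaps()` — per node, OLS on one
   indicator regressor per substate with no intercept, so β(node, state)
   *is* the node's mean activity in that state (an exact algebraic
   identity, tested as such). No nuisance regressors enter the design: the
   method names none, and the indicator-only design keeps β interpretable.
   z-maps standardize the in-state mean against the whole-scan mean and SD;
   excluding the state's own volumes from the reference is available via
   `exclude_self = TRUE` (the "rest of the scan" reading).
9. `paired_contrast()` — per-node paired t-tests on β differences with
   BH-FDR across nodes within a state (`fdr_bh()`); significant nodes split
   by sign into hyper-/hypo-activity masks. FDR control is within state
   across nodes. Note the statistical consequence: BH at α = 0.05 bounds
   the *expected false-discovery proportion*, so with ~100 null nodes the
   masks contain on the order of half a false node on average — exact
   set-identity with a planted truth is not a property FDR can promise.
10. `derive_heart_rate()` — EKG chain: decimate to 250 Hz if recorded
    faster (the recording convention is 5 kHz with a 250 Hz low-pass),
    half-wave rectify, wavelet band enhancement, R-peak detection with
    minimum height 7500 µV and minimum inter-beat distance 0.45 s,
    instantaneous heart rate 60/RR as a step function at 250 Hz, and
    window-mean down-sampling to 0.5 Hz (one value per TR = 2 s volume).
11. `pls2()`, `vas_change_and_tests()`, `pearson_with_df()`,
    `median_split()`, `order_effect_regression()`, `paired_ttest()` — the
    association layer: per-item paired tests with BH-FDR over the 25
    rating items, two-component SIMPLS partial least squares of regional or
    heart-rate change on rating change scores, correlations reported with
    their df (n − 2), a deterministic median split (ties go low), and OLS
    order-of-dosing checks.

`run_pipeline()` composes all stages from a single `run_config()` with
explicit seeds and writes plain-text outputs (affiliation TSV, sweep CSV,
summary/contrast/heart-rate CSVs, report JSON with provenance).

## Numerical and algorithmic choices

**Wavelet enhancement.** No published choice of wavelet family or levels
exists for this step, so the package uses a MODWT multiresolution band
filter with the Daubechies-4 wavelet: the detail levels whose nominal
pass-bands intersect the requested band (default 5–32 Hz, the conventional
QRS energy band; at 250 Hz these are levels 3–5) are recombined. The filter
is applied in the frequency domain through the squared-magnitude transfer
functions of the MODWT filters, which has two useful exact properties: the
transfer telescopes to unity when all levels are selected (perfect
reconstruction, tested at 1e−6) and it is zero-phase, so QRS peak positions
are preserved sample-exactly. The semi-automated manual adjustment of the
original detection procedure is inherently not reproducible and is replaced
by these fixed defaults.

**Peak pruning.** Candidate local maxima at or above the height floor are
pruned greedily in order of amplitude (ties: earlier index) so that no two
retained peaks are closer than the minimum inter-beat distance — a
deterministic reproduction of common `findpeaks` semantics.

**Heart-rate edges.** Before the first and after the last R-peak the
nearest RR value is extended, avoiding missing values at the scan edges; a
volume window containing no HR samples is reported as missing rather than
interpolated.

**Louvain restarts and quality.** The optimizer maximizes the dense
modularity matrix directly (local moves + aggregation). One hundred
restarts with seeded random node orders make the stochastic algorithm
reproducible; the returned partition always has Q at least that of the
trivial one-community partition. The compiled core keeps the full sweep
(11 thresholds × 100 restarts on an 840×840 matrix) under a minute.

**Ties and degenerate inputs.** Zero-variance volumes (similarity), nodes
(z-maps), difference vectors (paired tests), and empty states (GLM design)
are rejected or flagged by name rather than silently producing NaN. A
sweep in which every threshold empties the graph errors out — the
null-data case with noise, by contrast, simply retains zero substates.

## What the synthetic cohort emulates

`generate_cohort()` builds paired drug/placebo nodal series for each
participant (defaults: 14 participants, 112 nodes, 840 volumes, TR 2 s,
injection volume 240) as planted spatial pattern + condition effects +
i.i.d. Gaussian noise (sd 0.5 against unit-scale patterns; an AR(1) flag
exists, default off — real BOLD noise is autocorrelated, i.i.d. is the
simplest model sufficient for recovery testing).

The drug condition expresses five temporally persistent substates whose
windows tile the scan with a study-shaped occupancy profile: a dominant
pre-injection "baseline" state that returns late in the scan, two states
emerging after the injection, and two brief (<5%) states that the
retention rule discards — so three of five states survive, as in the
motivating design. The placebo condition revisits the *same* orthogonalized
spatial patterns but cycles them volume-by-volume: spatially structured,
temporally unpersistent activity. This is the design decision that makes
the subtraction matrix isolate drug-specific temporal similarity — and at
zero noise makes it *exactly* block structured, which is what lets the
sweep-recovery test demand an adjusted Rand index of 1 there. The
`placebo_persistent = TRUE` variant gives placebo the same windows, so the
two conditions differ only through the planted nodal effects (the matched
configuration for contrast-recovery and null-case tests), and
`balanced_substate_plan()` makes all five states substantial when the test
question is whether the sweep retains all of them.

Planted regional effects (`condition_effect()`) add a per-participant
amplitude (mean ± between-participant SD) to a node set during one state's
windows in one condition; the per-participant amplitudes are the ground
truth that ratings couple to. Heart-rate truth is a per-volume bpm plan
(baseline ~65 bpm, +12 bpm during the first post-injection state under
drug), rendered into beats by `rr_plan_from_bpm()` and into voltage traces
by `generate_ekg()` — a Ricker (Mexican-hat) pulse of 80 ms support per
beat, default amplitude 12 000 µV, a realistic chest-lead height
comfortably above the 7 500 µV detection floor.

Ratings (`generate_vas()`) live on the 0–1 grid in steps of 0.01. Each
participant-item has an anchor shared across conditions (test–retest
consistent), so anchor noise cancels in the change score; a coupled item's
drug rating adds `scale · (coef · z(source) + sqrt(1 − coef²) · ε)` plus
measurement noise. With `noise_sd = 0` the deterministic limit is returned
(zero coefficient ⇒ identical conditions; unit coefficient ⇒ change scores
correlated with the source at 1 up to 0.01-grid rounding); with moderate
noise the planted change-score correlation is approximately the
coefficient.

What passing these tests does *not* show about real data: the generator
has no head motion, no scanner drift, no haemodynamic autocorrelation, no
spatially correlated noise, and its states are exactly contiguous and
identical across participants. Recovery results here validate the
*machinery*, not the effect sizes one should expect from real cohorts.

## Problem sizes used in the test suite

Unit tests run on a miniature cohort (4 participants, 30 nodes, 120
volumes, five balanced states) where every stage completes in milliseconds.
The end-to-end recovery checks run at the full study scale — 14
participants × 112 nodes × 840 volumes with the complete 11-threshold ×
100-restart sweep — and the Monte-Carlo recovery checks use 100 simulation
seeds (contrast masks) and 100 seeds × 200 synthetic participants (PLS
loading signs). These sizes were chosen as the smallest that exercise the
method at its intended scale.

## SIMPLS conventions

`pls2()` follows the SIMPLS contract of the original MATLAB routine:
column-centering of X and Y, no unit-variance scaling, successive weight
vectors from the SVD of the deflated cross-product matrix with an
orthonormal loading basis for deflation, X scores normalized to unit
length. Signs are fixed deterministically — each component is flipped so
its largest-magnitude X loading is positive. One consequence worth knowing:
absolute loading signs are only anchored when the dominant coupled
predictor is positively coupled; a dominant negative coupling flips the
whole component, which is a change of convention, not of model fit. The
per-component score correlation is reported with df = n − 2; a component
left with degenerate scores (outcome fully explained by earlier
components) reports `NA`.

## Known limitations

- The Louvain optimizer works on the dense matrix; it is intended for
  time×time matrices (hundreds to ~2000 volumes), not for sparse graphs
  with 10⁵+ nodes.
- The semi-automated, visually guided steps of the original EKG procedure
  are replaced by fixed defaults; traces with pathological morphology may
  need a different band or height floor.
- The subtraction-matrix approach needs paired conditions on a shared
  volume grid; scans of unequal length are out of scope.
- Occupancy denominators treat all volumes as usable unless an explicit
  exclusion mask is supplied; upstream scrubbing/interpolation is assumed
  done.
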