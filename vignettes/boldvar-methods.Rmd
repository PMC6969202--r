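---
title: "Methods: signal variability, entropy calibration, network efficiency, and brain-behavior PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal variability, entropy calibration, network efficiency, and brain-behavior PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldvar)
```

This vignette is the package's account of the science it implements: the
models, the conventions chosen where the literature leaves room, and what
the synthetic-data generator does and does not emulate.

## Signal variability and complexity

Every metric is computed on z-normalized series (mean 0, SD 1, divisor
n − 1). Normalizing first makes the metrics amplitude-free and makes the
entropy tolerance r·SD reduce to r. The same n − 1 convention is used
everywhere an SD appears: z-scoring, the SD metric, the entropy tolerance,
and the calibration SE. `znormalize()` refuses constant columns by ROI
name, since a flat series has no meaningful variability scale.

**MSSD** is the mean of squared successive differences,
δ² = Σ(xᵢ₊₁ − xᵢ)²/(n − 1) for n time points. Unlike the variance it is
insensitive to slow drifts of the mean. For a z-scored stationary AR(1)
process with lag-1 coefficient φ, the population MSSD is 2(1 − φ) — the
analytic anchor used throughout validation.

**Sample entropy** follows the PhysioNet convention: Chebyshev (max-norm)
distance between templates, self-matches excluded, each unordered pair
counted once, and templates of length m and m + 1 both drawn from start
positions 1..(n − m) so the two counts range over the same pairs. The pair
counting is compiled (C++) because the calibration grid evaluates tens of
thousands of series; the test suite checks it against an independent
matrix-algebra implementation to 1e−12.

Two deliberate value-level choices:

- An estimation **failure** (A = 0 or B = 0, i.e. no matching templates at
  one of the lengths) returns `NA_real_` rather than raising. The
  calibration grid *counts* failures over thousands of voxels, so failure
  must be data, not control flow.
- A constant series returns 0 (all templates match at tolerance 0), which
  keeps the degenerate limit well-defined.

A caution on folklore: sample entropy is *not* monotone in m on a fixed
series. Only A ≤ B is guaranteed per m (so SampEn ≥ 0 whenever defined);
the conditional match probability A/B can rise or fall as m grows, and on
simulated AR(1) series it rises more often than not. The test suite
asserts the deterministic facts, not the folklore ordering.

## Entropy parameter calibration

Sample entropy needs a pattern length m and tolerance r. The package
calibrates them on noise-reference (CSF) voxel series, where entropy
estimates should be stable: for each (m, r), entropy is computed for every
reference voxel of every participant, and the per-participant standard
error is

SE = 1.96 · (σ_SampEn / mean SampEn)²

with σ and the mean taken across that participant's non-failed voxels.
This squared-coefficient-of-variation form is dimensionally unusual but is
the published convention this calibration follows; `squared = FALSE` gives
the unsquared variant for sensitivity analyses. A cell is **acceptable**
when the median SE across participants is below 0.1 *and* no estimation
failure occurred in any voxel of any participant. The default grid is
m = 1..4 × r = 0.05..0.80 (step 0.05); longer patterns are pointless
because the SE criterion already fails everywhere beyond m = 4 at this
series length.

Numerical edge cases: a participant whose mean voxel entropy is 0 (e.g.
constant reference signal) has an undefined SE; the affected cell is
marked unacceptable rather than raising, because a degenerate reference
carries no calibration information. Acceptability is monotone in the
threshold by construction.

Entropy is then averaged cell-wise over a selected set of acceptable
conditions. The shipped default, `default_entropy_conditions()`, averages
the m = 2 conditions with r from 0.25 to 0.65: r = 0.20, though
acceptable, contrasts with the other tolerances in its entropy estimates,
and the exclusion is therefore a configuration entry (it was a data-driven
choice, not a rule — users with different data should revisit it). Failed
cells are excluded pairwise from the average, preserving the subject;
exclusions are counted and warned about. Selecting a condition the grid
does not flag acceptable is an error unless explicitly overridden.

## Structural network efficiency

Global efficiency of a weighted graph is the average inverse
shortest-path length over ordered node pairs, with edge lengths the
reciprocals of the weights and 1/∞ := 0 for disconnected pairs. Shortest
paths use Dijkstra's algorithm (via igraph); the suite checks equality
with a Floyd–Warshall oracle on hundreds of random graphs. A complete
unit-weight graph has GE exactly 1, an edgeless graph 0.

Conventions: tractography output can be asymmetric, and since GE is used
as an undirected summary, weights are symmetrized by the arithmetic mean
of (i, j) and (j, i) before the computation (directed mode is available).
Implausible edges are removed beforehand by zeroing weights absent from a
binary anatomical-presence (CoCoMac-style) mask. Because efficiency
correlates with head motion in typical samples, `residualize()` regresses
a covariate (mean framewise displacement) out by OLS and adds the grand
mean back — the mean restores an interpretable scale; downstream PLS is
translation-insensitive, so this is cosmetic but aids reporting.

## Partial least squares

Both PLS flavours are SVDs of a cross-block matrix; singular values
measure captured covariance, and covariance explained per latent variable
(LV) is d²ₖ/Σd².

- **Mean-centering PLS** decomposes the groups × brain-variables matrix of
  group means after removing the *grand mean of the group means* from each
  column. Grand-mean removal (rather than group-wise variants) is the
  default because it asks exactly the "which contrast between groups best
  explains the brain data" question; the left singular vectors are the
  group contrasts (design saliences).
- **Behavioral PLS** stacks the per-group behavior × brain Pearson
  correlation matrices row-wise and decomposes the stack. Right singular
  vectors are brain saliences; the left vectors, in per-group blocks, are
  behavior saliences. Brain scores are X·V; behavior scores project each
  subject's z-scored behavior row onto their group's block. With one group
  and one behavior variable the decomposition reduces, exactly, to the
  normalized correlation vector — a closed-form identity the tests assert.

Behavior variables are z-normalized before analysis, and pairs correlated
above |r| = 0.8 trigger a warning: strongly redundant behavior columns
(e.g. a questionnaire's subscales alongside its total) bias the
decomposition, and a total score should be preferred.

**Sign convention.** SVD signs are arbitrary, so per LV the
largest-magnitude element of the brain salience is made positive.
Refitting without resampling is therefore bit-identical.

**Permutation test.** Subject rows of the brain matrix are reshuffled
against the fixed behavior/design block and the singular values refitted;
p per LV is the proportion of permuted singular values ≥ the observed one.
The default applies (count + 1)/(n_perm + 1) smoothing so p is never
exactly 0 (standard exact-test practice; the raw proportion is available
by flag). Permutation is across the whole sample by default — breaking
both group membership and behavior linkage — with within-group permutation
as an option. The defaults are 1000 permutations and 500 bootstrap
samples.

**Bootstrap.** Subjects are resampled with replacement *within* group
(stratified, preserving group sizes). Each bootstrap solution is aligned
to the original by orthogonal Procrustes rotation of the singular vectors
(axis reflections and rotations between resamples would otherwise inflate
the SDs; sign-matching alignment is available instead). The bootstrap
ratio BSR = original salience / bootstrap SD flags reliable brain
variables at |BSR| ≥ 2, approximately a 95% criterion; behavior/design
saliences get percentile 95% CIs. A resample that zeroes a column's
variance in some group is redrawn, with a capped retry count.

## Univariate statistics

`pooled_t()` computes the equal-variance two-sample t identically from
raw vectors or from (n, mean, SD) summaries, so published summary tables
can be re-tested; `chi_square()` is Pearson's test without continuity
correction; `fisher_z_compare()` compares independent correlations on the
atanh scale; `variance_ratio()` is the plain F = sd₁²/sd₂² on
(n₁ − 1, n₂ − 1) df. All p-values are two-sided. One documented
discrepancy: for group-score SDs of 1.18 vs 0.94 (n = 20, 17) the
standard ratio gives F = 1.58, yet published analyses of such data have
reported F(19, 16) = 2.29 — whatever test produced that value is not
identifiable from its description, so the package implements the standard
ratio and leaves the difference documented rather than reconciled.

## The synthetic-data generator

The generator's job is to produce inputs with exactly the statistical
structure the analysis assumes, so that every stage is testable without
imaging data.

- **BOLD series** are stationary AR(1) processes, z-normalized. AR(1) is
  the minimal process whose variability and complexity are tunable by one
  knob with an analytic anchor (MSSD = 2(1 − φ) at unit variance). ROIs
  carrying nonzero planted-salience weight share a subject-level
  coefficient (drawn from `ar_range`, default 0.1–0.6, jittered per ROI
  with SD 0.03); null ROIs draw independent coefficients. The shared
  coefficient is what makes the planted pattern *distributed* — a set of
  regions whose variability covaries across subjects — which is the
  structure a brain-behavior PLS is designed to detect, and which real
  regional variability exhibits. With fully independent ROI columns the
  in-sample correlation noise (∼1/√n per element over 82 regions) would
  bound salience recovery near cosine 0.6 at n = 40 regardless of effect
  size; a distributed pattern is both more realistic and actually
  recoverable.
- **CSF references** are iid standard-normal series (default 30 voxels ×
  180 time points): white noise is entropy-stable wherever estimation
  succeeds, which is precisely what a calibration reference should be.
- **Structural matrices** draw a shared symmetric presence mask with a
  fixed edge count (density × number of node pairs — exact density, no
  degenerate draws) and per-subject non-negative weights scaled by a
  per-subject efficiency knob, giving a known GE ordering (exactly linear
  in the knob on complete graphs).
- **Behavior tables** project each subject's metric row onto the planted
  salience, z-score the latent, and build each column as
  effect_size · sign · latent + noise, z-normalized — positive signs for
  efficiency, age and IQ, negative for severity, matching the continuum
  structure the analyses target. `effect_size = 0` yields null data for
  type-I-error studies. A head-motion column uncorrelated with the latent
  is always appended.

Defaults mirror the study conditions the package's analyses assume: groups
of 20 and 17, 82 cortical ROIs, 180 TRs, a planted support of
⌈0.23 · R⌉ regions (about the fraction of regions such analyses flag as
reliable), effect size 3 with noise SD 0.5 ("strong effect"). All
generators are pure functions of (config, seed).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamics and scanner noise spectra, head
motion beyond a nuisance covariate, spatial autocorrelation beyond the
planted shared factor, non-stationarity, censoring artifacts, and any
preprocessing pipeline. Results on synthetic data validate the
*estimators*, not the neuroscience.

## Validation sizes and numerical tolerances

Validation uses desk-scale problem sizes chosen to make the checks sharp
yet quick: entropy oracle equivalence on 100 seeded series (n ≤ 200) at
1e−12; efficiency vs a Floyd–Warshall oracle on 200 random graphs
(R ≤ 12) at 1e−12; MSSD vs 2(1 − φ) over 100 seeds × 4 φ values at an
absolute tolerance of 0.06 — chosen to cover the finite-length lag-1
autocorrelation bias (≈ 2(1 + 3φ)/T, up to ≈ 0.04 at φ = 0.9, T = 180)
plus Monte-Carlo error, since the closed form is asymptotic; calibration
structure on 6 subjects × 20 voxels; PLS recovery at n = 40 × 82 ROIs with
200 permutations, and type-I error over 200 null replicates judged against
the exact binomial 95% band around 0.05.

## Known limitations

- Sample entropy is single-scale; no multiscale (coarse-grained) variant.
- Mean-centering PLS offers grand-mean centering only; other centering
  schemes common in PLS software are not implemented.
- The behavioral PLS assumes complete cases; estimation failures must be
  resolved (by condition averaging or exclusion) before fitting.
- Permutation p-values for LVs beyond the first inherit the usual
  non-independence caveats of successive singular values; interpret them
  qualitatively.
- No NIfTI ingestion: inputs are plain-text matrices extracted upstream.
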