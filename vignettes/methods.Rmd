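---
title: "Models and methods behind actionrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind actionrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(actionrsa)
```

# Overview

`actionrsa` analyzes the representational geometry of observed actions in a
condition-rich design: ~90 naturalistic action clips, each a distinct
condition, shown repeatedly across two measurement sessions. The analysis
currency is the representational dissimilarity matrix (RDM): a symmetric
matrix of pairwise dissimilarities between stimuli, compared across data
sources by rank statistics on its vectorized upper triangle (fixed row-major
pair order, diagonal excluded).

The pipeline has five stages: experimental design generation, synthetic
data simulation, RDM construction, model fitting (RSA, joint rank
regression, variance partitioning), and group-level resampling inference.
This vignette records the model assumptions, the tunable parameters and why
their defaults are what they are, and the numerical decisions made where the
design was genuinely open.

# Experimental design generation

## Serially balanced sequences

A type 1 index 1 serially balanced sequence over `n` trial types is a
circular sequence of length `n^2` in which every ordered pair of types —
self-pairs included — occurs exactly once among circular adjacencies. It
exactly counterbalances first-order carryover. For even `n` the package
additionally requires the sequence to decompose into `n` consecutive blocks,
each a permutation of the alphabet, so that runs built from consecutive
blocks show every type equally often.

**Construction.** The classical route — a Williams row-complete Latin
square with rows chained end-to-start — cannot produce the circular object:
for any terrace-translate square the junction successor map is
`i -> i + n/2 (mod n)`, which splits into `n/2` two-cycles, so the rows
never chain into a single circle. The package instead runs a randomized
backtracking depth-first search over the full sequence (implemented in C++),
with block-membership and edge-usage constraints and Warnsdorff candidate
ordering (fewest unused exits first). The search is complete: exhausting it
proves infeasibility.

**The n = 4 exception.** Exhaustive search shows that *no* block-structured
circular sequence exists for a 4-type alphabet. `actionrsa` falls back to
the unblocked Eulerian solution there, with a warning; every other even
alphabet tested (2, 6, 8, ..., 24) has solutions found in under a second.
Odd alphabets cannot carry the block structure at all (self-pairs can only
sit at block junctions, and an odd alphabet cannot host all `n` of them
there), so they always use the plain Eulerian circuit.

## Timing

Interstimulus intervals are `min_isi + Exp(mean_isi - min_isi)`, truncated
at `3 * mean_isi`, iteratively rescaled so the ISI sum equals
`n_trials * mean_isi` exactly, and quantized to a 0.1 s grid by
largest-remainder apportionment (which preserves both the exact total and
the floor). The exact-total constraint is a deliberate design choice: it
makes the run duration a constant of the configuration —
`5 s lead-in + 3 context trials * (2.5 + 2.5) s + 100 trials * 2.5 s +
250 s ISI + 15 s tail = 535 s` at defaults — rather than a random variable.
The truncation point (3x the mean) is our choice; only the distribution
shape, mean, and floor are externally fixed.

Design efficiency is estimation efficiency, `1 / trace(C (X'X)^{-1} C')`,
with the design matrix built at 0.1 s resolution by convolving per-condition
boxcars with a canonical double-gamma response (peak 6 s, undershoot 16 s,
undershoot ratio 1/6), sampled at a 1 s repetition time, with an intercept
column excluded from the contrasts. The default contrast set is one identity
contrast per condition. Singular designs score 0 with a warning;
`select_best_design()` takes the argmax over seeded candidates, ties to the
lowest index.

## Probe repair and run partitioning

A semantic probe asks about the preceding clip, so a probe directly after a
fixation or another probe is meaningless; the repair converts every such
trailing probe to a fixation trial in one left-to-right scan (a probe whose
predecessor was itself just converted is still repaired). Runs are prepended
with the previous run's final three trial categories — replayed from a
separate preparatory exemplar pool so no exemplar repeats within a run —
and the first run wraps around to the session's end.

## Arrangement subset planning

The multiple arrangements task measures a full-set arrangement first, then
12 subsets of 30. Candidate subset plans are built by permuting the stimulus
list and slicing it; each candidate is scored by the number of distinct
stimulus pairs co-occurring in at least one subset, and the best of 1000
candidates wins. The full set is prepended, guaranteeing every pair at least
one measurement.

# The synthetic-data generative model

The simulator's purpose is parameter recovery with known ground truth, so
its construction is chosen to make the *measured* quantity — the
split-session correlation RDM of unit-z-scored patterns — provably linked
to the latent truth.

**Latent geometries.** Each model geometry is a correlation-distance RDM
over an `m x q` latent feature matrix (default `q = 25`): per-feature
category effects (SD 1) plus exemplar-level noise (SD 1.5), alternately
row-centered and column-z-scored until both hold to ~1e-10. The exemplar
SD default is calibrated so that two independently drawn geometries sharing
only the category partition correlate below 0.1 (Spearman, at the default
18 x 5 stimulus set); a nonzero target correlation between models is hit by
mixing a shared latent component, with the mixing proportion solved
numerically against the realized matrices.

**From latents to patterns.** The weighted latent features (columns scaled
by `sqrt(w_m)`) are mapped to `n_units` channels by a single shared linear
map with orthonormal rows, whose per-unit response variances are then
*exactly equalized* by Givens rotations (rotations preserve the map's
row-Gram, hence the condition geometry, while trading variance between unit
pairs). The balancing and equalization together make the downstream
z-scoring of unit profiles a pure rescaling, so with zero noise the
split-session RDM reproduces the generating model RDM to rank accuracy
better than 0.999. A classical-metric-scaling construction cannot achieve
this: unit z-scoring forces the observed geometry to be the
double-centered, diagonal-normalized transform of whatever similarity
matrix is targeted, which empirically caps the rank agreement near 0.94.
This substitution is the package's own design choice, made so the
noiseless-recovery contract is actually attainable.

**Noise model.** Independent Gaussian noise per subject x session x unit,
`noise_sd` in units of the (unit-variance) latent scale; the default 0.6
yields split-half model correlations around 0.3-0.5 and a group noise
ceiling well below 1 — a deliberately realistic regime in which the
20-subject, 500-unit recovery of mixture-weight *ordering* still succeeds in
>= 95% of seeds.

**What the simulator does not emulate.** Subject-specific topographies
(functional alignment is assumed already applied; all subjects share one
latent-to-unit map), hemodynamics and trial-level time series (patterns are
simulated at the session-coefficient level), and stimulus-driven gaze
saliency (gaze prototypes are smooth random walks, unrelated to the neural
truth — which is exactly what makes the gaze model a useful negative
control in the synthetic pipeline). A green end-to-end test therefore
establishes the correctness of the *analysis machinery*, not the realism of
any particular physiological assumption.

## Behavioral, gaze, and semantic simulators

Arrangement trials lay out each subset's sub-RDM by classical metric
scaling, randomly rotate/reflect it, scale it into the arena, and add
isotropic placement jitter (default 10 px inside a 400 px arena). Since only
2-D information survives a single arrangement, round-trip recovery is exact
only for 2-D-embeddable geometries; for general RDMs the aggregated sparse
subsets approximate the geometry, mirroring the real task's behavior.

Gaze trials copy a per-stimulus prototype path with added noise and
geometric blink gaps (mean ~170 ms); `blink_prob = 1` censors whole trials
and exercises the downstream exclusion path. Annotations draw 2-5 verb and
3-6 nonverb tokens per stimulus from category vocabularies whose embedding
vectors cluster around unit-norm category centroids (scatter 0.4), matching
the label-count ranges reported for manually annotated clips.

# RDM construction decisions

- **Split-session RDMs:** `d_ij = 1 - (c_ij + c_ji)/2` where `c` is the
  cross-session Pearson correlation matrix. Averaging the two triangles
  resolves the asymmetry of cross-correlation; the diagonal (`1 - c_ii`,
  nonzero under noise) is stored but never vectorized.
- **Unit z-scoring** uses the population SD; constant units become zero
  with a warning rather than an error (a dead channel should not abort a
  session).
- **Arrangement distances** are averaged in raw screen pixels with no
  per-trial rescaling, exactly as logged; an optional RMS normalization
  flag exists but defaults off.
- **Gaze preprocessing:** invalid spans are linearly interpolated from
  flanking valid samples; the rolling median window is the nearest odd
  sample count to 84 ms at the native rate (85 samples at 1000 Hz), edges
  handled by shrinking windows; decimation is the per-frame-bin mean (the
  prior median filter acts as the anti-aliasing step). Participants whose
  mean inter-block RDM correlation falls below r = .1 are excluded;
  `min_interblock_r = -1` turns the filter off.
- **Semantic RDMs:** stimulus vector = unweighted mean of its token
  vectors; distance = `1 - cosine`. Tokens missing from the embedding table
  are dropped with a warning; a stimulus losing all tokens is an error
  naming it.
- **Feature RDMs** default to correlation distance; Euclidean and cosine
  are available, since the appropriate metric for externally computed
  feature spaces (e.g., motion energy) is not canonical.

# Model fitting

All comparisons operate on vectorized upper triangles. Rank transforms use
average ranks for ties throughout.

**Joint regression.** Model RDM vectors are ranked and standardized; the
response is ranked and standardized too (a flag restores raw-response
regression). The ranked response makes the single-model fit exactly
Spearman `rho^2`, so joint `R^2` values sit on the same scale as the RSA
maps. Fits are OLS with intercept; `R^2 = 1 - SSE/SST`.

**Variance partitioning.** `unique R^2 = full R^2 - nested R^2`, computed
per subject and averaged afterwards. `joint_regression_r2()` rejects
perfectly collinear model sets by name, but `variance_partition()`
tolerates aliasing (dropping dependent columns): a model duplicated outside
its group must yield zero unique variance, not an error. Negative unique
`R^2` (suppression) is reported as computed, never clipped in tables.

**Noise ceiling.** Leave-one-out intersubject Spearman correlation,
averaged across subjects on the Fisher-z scale and back-transformed
(boundary values are clamped at `1 - 1e-15` before `atanh` so identical
RDMs yield a ceiling of 1 rather than an error). The ceiling-normalized
share of a joint fit is `R^2 / r_ceiling^2`, using the squared ceiling
correlation as the bound on explainable variance.

**Neighborhood maps.** Searchlight neighborhoods are an explicit input
(center to member units); the package never processes cortical meshes.
Neighborhoods with fewer than two units produce a missing value, logged in
the output table.

# Resampling inference

- **p-value convention:** add-one correction `(1 + #{null >= observed}) /
  (1 + N)`, with `>=` on ties — conservative, and p is never zero. All
  alternatives are one-sided (greater), matching directional RSA
  hypotheses.
- **Sign-flip permutation** operates on Fisher-z transformed subject
  correlations; each permutation flips each subject's sign independently.
  An exhaustive mode enumerates all `2^n` patterns for small n, used as the
  oracle in tests.
- **Re-centered bootstrap** for `R^2`: subject values are resampled with
  replacement, and the bootstrap distribution of the mean is re-centered by
  subtracting the observed mean before computing the exceedance — the
  appropriate correction for a statistic that is positively biased above
  zero.
- **Condition-label permutation** shuffles the model RDM's rows and columns
  jointly. When the statistic is Spearman RSA, a fast path ranks the neural
  vector once and only re-ranks the permuted model vector.
- **Bootstrap CIs** are percentile 2.5/97.5 intervals (not BCa), over
  subjects, or over subjects and stimuli jointly; in the latter case cells
  pairing a stimulus with its own duplicate are masked `NA` and excluded
  from the vectorized comparison, as duplicate pairs carry zero distance by
  construction, and the statistic callable receives the stimulus resample
  index so model RDMs can be aligned identically. Draws on which the
  statistic is undefined are discarded and counted; more than 10% discards
  aborts.

Type-I calibration of the sign-flip and condition-label tests sits inside
[0.03, 0.07] at a nominal alpha of 0.05 over 1000 null replicates (500
permutations each), and rejection rates rise monotonically with simulated
effect size; both properties are asserted in the acceptance test suite.

# Numerical choices and degenerate inputs

- Times are stored at 0.1 s resolution; ISI quantization preserves exact
  run totals by largest-remainder apportionment.
- RDM symmetry is validated at 1e-9 and symmetrized by averaging.
- Ties in all rank transforms use average ranks; argmax selections break
  ties toward the lowest candidate index.
- Degenerate metric-scaling solutions (tiny arrangement subsets) are
  zero-padded to 2-D; fully censored gaze trials are excluded and counted;
  zero-variance response patterns, constant RDM vectors, zero-norm
  embedding vectors, and unmeasured stimulus pairs raise errors naming the
  offending stimulus or pair.
- Every stochastic function takes an explicit seed and restores the
  caller's RNG state; rerunning any stage with the same configuration and
  seed is bit-reproducible.

# Scaling of the test suite

Unit and property tests run on reduced worlds (6 x 3 stimulus sets, tens of
units, hundreds of resamples) to keep the suite fast; the acceptance tests
run the design combinatorics at the full 20-type / 90-stimulus scale, the
statistical calibration at 1000 replicates x 500 permutations, and the
parameter-recovery study at 50 seeds x 20 subjects x 500 units, which
together take about a minute.

# Known limitations

- The sequence search is stochastic with a complete fallback; for very
  large even alphabets (n > 30 or so) the block-structured search may need
  more restarts than the default budget.
- The variance-equalized linear map makes all units equally informative;
  real measurement channels are not, so absolute noise-ceiling values in
  the simulator should not be read as predictions for real data.
- Inverse multidimensional scaling (re-estimating a high-dimensional
  configuration from sparse arrangements) is deliberately out of scope; the
  aggregation is plain sparse averaging.
- The gaze simulator shares one prototype path per stimulus across
  participants, so inter-participant gaze consistency is high by
  construction; the reliability filter is exercised by constructing
  inconsistent participants explicitly in tests.
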