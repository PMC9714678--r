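---
title: "Methods: resting-state DMN connectivity and graph topology with dmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state DMN connectivity and graph topology with dmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dmnet analyzes resting-state BOLD fMRI at the level of region-of-interest
(ROI) time series. Its reference design is the 12-node rodent default mode
network (DMN): six bilateral regions (auditory, orbital, parietal
association, prelimbic, retrosplenial cortices, and hippocampus), sampled
as 180 volumes at TR = 2 s. The pipeline runs

1. temporal preprocessing with motion-based subject exclusion,
2. Pearson functional connectivity (FC),
3. weighted graph topology across proportional sparsity thresholds,
   with small-world normalization against degree-preserving null networks,
4. group inference: the network-based statistic (NBS) on edges and
   FDR-corrected t-tests on topology metrics.

Because a synthetic cohort generator with exactly known ground truth is
part of the package, every downstream stage is testable without any
imaging data.

## The synthetic cohort generator

`cohort_config()` + `generate_cohort()` produce two groups (control,
treated) of subjects, each a T x N time-series matrix plus a T x 6 motion
trace.

**Signal construction.** Resting-state connectivity analysis concerns the
0.01–0.08 Hz band, so the generator builds signals directly inside it:
Gaussian innovations are ideal-filtered to 0.01–0.08 Hz, *empirically
whitened* (their sample covariance is transformed to the exact identity),
and mixed by a Cholesky-type factor of the target correlation matrix. The
consequence is exact by construction: with zero noise and drift, the
sample correlation of a generated series *equals* the subject's stored
`ground_truth_r`, at any series length. Linear drift (per-ROI slope ~
Normal(0, `drift_slope_sd`)) and white measurement noise (`noise_sd`) are
then added. Between-subject variability therefore arises from the noise
realizations, not from finite-sample correlation error; this makes
recovery tests sharp, at the cost of underrepresenting the biological
between-subject variance of real cohorts (see Limitations).

**Attenuation.** White noise biases sample correlations toward zero. After
band-pass filtering, only the in-band fraction q = (0.08 − 0.01)/0.25 =
0.28 of the noise variance survives, so measured FC concentrates around
`ground_truth_r` / (1 + q sigma²). The test suite checks both the
low-noise limit and this analytic attenuation at the default noise level.

**Defaults and why.** Values the study design fixes: N = 12 ROIs, T = 180
volumes, TR = 2 s, 12 subjects per group. Values chosen once as realistic
for rodent rs-fMRI, configurable and not derived from any dataset:
homotopic (left–right) base correlation 0.6 and background 0.3 with
jitter SD 0.03 (homotopic connectivity is the dominant feature of rodent
DMN FC; the jitter breaks edge ties and the matrix is projected to the
nearest positive-semidefinite correlation matrix); `noise_sd = 0.25`
relative to unit-variance signal; `drift_slope_sd = 0.002` units/volume
(drift amplitude a third of the signal SD over the run);
`motion_excursion_prob = 0.15`. Treated subjects use the base matrix plus
`planted_edges` deltas; a configuration whose treated target loses
positive semidefiniteness is rejected with the offending edge named.

**Motion traces.** Smooth bounded random walks scaled to stay well below
the exclusion thresholds; with probability `motion_excursion_prob` a
Gaussian bump is injected whose peak lands between 1.1 and 1.8 mm (or
degrees), guaranteeing an above-threshold excursion.

## Preprocessing

Stages are applied per subject in a fixed order mirroring conventional
temporal pipelines: motion QC, linear detrend, band-pass, nuisance
regression. All three data stages are linear operators, verified as such
in tests.

* **Motion QC** excludes a subject entirely when any translation sample
  exceeds 1 mm on any axis or any rotation exceeds 1 degree (defaults;
  configurable). Individual-volume scrubbing is deliberately not
  implemented — inclusion is per subject.
* **Detrending** subtracts the per-column OLS line; exact for linear
  inputs, idempotent.
* **Band-pass** is a Butterworth filter of order 2 applied
  forward–backward (`signal::filtfilt`), hence zero-phase — important
  because phase shifts at T = 180 would distort correlations. On a
  180-sample, TR = 2 s series, a 0.04 Hz sinusoid retains 99% of its RMS
  amplitude; 0.2 Hz retains < 1%; 0.002 Hz retains < 10%. The order is a
  parameter; the defaults are validated by frequency-response tests.
* **Nuisance regression** removes an intercept plus the six raw motion
  parameters per ROI (no derivatives or squares, and the regressors are
  not themselves band-passed — a deliberate mismatch-of-band caveat noted
  here). Degenerate (constant) regressors are dropped with a warning, so
  zero motion reduces to mean-centering.

## Connectivity and thresholding

FC is the Pearson correlation of preprocessed ROI pairs; the diagonal is
set to zero since self-connections are meaningless in every downstream
metric and would create zero-length edges under the distance transform.
Edgewise statistics operate on Fisher z = atanh(r) values (clipped to
|r| <= 1 − 1e−12); graph metrics operate on the correlation scale, which
the `1 − w` distance transform presumes.

Proportional thresholding keeps the `round(s·N(N−1)/2)` strongest edges
at each sparsity s in {0.10, 0.15, ..., 0.50} (nine levels). Negative
correlations are zeroed before ranking by default (`"absolute"` and
`"keep"` are available): under the `1 − w` transform a negative weight
would yield a distance above 1 and the efficiency formulas presume
weights in [0, 1]. Retained weights are capped at 1 − 1e−6 so edge
distances stay strictly positive. Rounding is conventional half-up
(`floor(x + 0.5)`), and ties are broken deterministically by (weight
descending, row, column), so runs are exactly reproducible. If fewer
positive edges exist than requested, all available ones are kept with a
warning — the network may then be disconnected.

## Topology metrics

With edge distance `L_ij = 1 − w_ij` and shortest-path lengths from
Dijkstra's algorithm:

* global efficiency `E_glob = (1/(N(N−1))) Σ_{i≠j} 1/L_path(i,j)`,
* nodal efficiency `E_i = (1/(N−1)) Σ_{j≠i} 1/L_path(i,j)`,
* nodal local efficiency `E_i_local`: the global-efficiency formula on the
  subgraph induced by i's neighbors (i excluded, weights retained), zero
  when the degree is below 2; `E_loc` is its mean,
* binary clustering `C_i = 2T_i/(K_i(K_i−1))` (T_i = edges among
  neighbors), `C_p = mean(C_i)`,
* characteristic path length `L_p`: the mean over *connected* pairs, with
  the number of disconnected pairs reported alongside.

Disconnected pairs contribute 0 to efficiencies (1/∞ = 0) and are
excluded from `L_p`'s average; a network with no edges has no defined
`L_p` and errors. Since weights live on the correlation scale, distances
can be below 1 and `E_glob` can exceed 1; it is reported unnormalized.
Three identities — mean(E_i) = E_glob, E_loc = mean(E_i_local),
C_p = mean(C_i) — are exact and asserted on every profile in the tests.
Clustering is computed combinatorially on the binary support because that
is its defining formula; the efficiency and path measures use the
retained weights.

## Small-world normalization

`random_ensemble()` builds matched nulls by degree-preserving double-edge
swaps (about 10 successful swaps per edge) followed by random reassignment
of the original weight multiset to the rewired edges; degree sequence,
edge count, and weight multiset are preserved exactly. Graphs that cannot
be rewired (complete, or with fewer than two independent edges) fall back
to weight permutation with a warning; hub-degenerate graphs like stars
rewire to themselves, giving a zero-clustering null, in which case gamma
is undefined and the network is reported as not small-world with a
reason.

gamma = C_p/C_p_rand, lambda = L_p/L_p_rand, sigma = gamma/lambda, with
the ensemble means as the normalizers (n_rand = 100 by default). The
small-world call is gamma > 1 together with lambda within 1 ± 0.15 or
sigma > 1; the tolerance is exposed because "lambda ≈ 1" has no canonical
width. Whether small-worldness should be judged per sparsity or on
AUC-summarized metrics is genuinely open; the per-sparsity indices and
the trapezoidal area under the curve over [0.1, 0.5] are both emitted.

## Group statistics

**Edgewise tests.** Two-sided two-sample t-tests per edge on Fisher-z FC
(pooled variance by default, Welch optional), treated minus control.

**NBS.** Edges with uncorrected p below the primary threshold (default
0.05) form a graph; its connected components are candidate effects. Their
statistic is compared against the maximum over `n_perm = 1000` random
relabelings, giving `p_fwe = (1 + #{null ≥ observed})/(1 + n_perm)` — the
add-one estimator, which cannot produce zero. Two component statistics
are implemented: **extent** (edge count, the default) and **intensity**
(sum of |t| over the component). At this network size (66 edges) the
extent null is concentrated on small integers; the resulting ties make
the max-statistic test conservative, and when a planted effect is strong
the observed extent saturates near the true component size while
imbalanced permutation splits partially reproduce it. The intensity
statistic has a continuous null and separates strong components cleanly;
the package's simulation studies therefore use intensity, while extent
remains the default for conventional reporting. The primary threshold is
a free parameter with no canonical value; it is recorded in every
result object.

**Topology comparisons.** t-tests per metric at each sparsity and on each
AUC summary, with Benjamini–Hochberg correction applied within families:
all global metrics form one family, nodal metrics one family per sparsity
plus one for nodal AUCs. The family definition is a reporting choice (no
canonical convention exists) and is visible in the output's `family`
column. Metrics with zero variance in both groups (e.g. C_p = 0 at the
sparsest threshold for every subject) are reported as t = 0, p = 1 rather
than an error.

Edge classification (cortico-cortical / cortico-subcortical /
subcortico-subcortical) uses the node table in `dmn_rois()`, where only
the hippocampus is subcortical; the table is an ordinary tibble a user
can replace.

## Problem sizes used in the validation suite

The test suite exercises: metric equivalence against brute-force
Floyd–Warshall and explicit subgraph enumeration on 1000 random weighted
graphs of up to 6 nodes; small-world discrimination over 100
ring-lattice (N = 12, k = 4, 10% rewiring) and 100 density-matched
Erdős–Rényi graphs with 100-network ensembles; family-wise error
calibration over 200 null cohorts and power over 100 planted-effect
cohorts (5-edge path, delta r = −0.3, 12/group), both at 200 permutations
per cohort — a deliberately reduced permutation count for the simulation
studies, with the full 1000 used for single analyses. These sizes balance
Monte-Carlo resolution against a test suite that completes in minutes.

## What passing tests do and do not show

The generator produces band-limited stationary Gaussian signals with
exactly known correlation structure, independent white noise, linear
drift, and smooth motion — it omits hemodynamic response shape,
physiological (cardiac/respiratory) confounds, spatially correlated
noise, non-stationarity, and true biological between-subject variance in
connectivity. Passing recovery and calibration tests therefore validates
the *computational pipeline* (preprocessing contracts, metric formulas,
permutation machinery), not the behavior of these methods on real rat
data, where effect sizes, motion-FC coupling, and variance components are
less benign. Synthetic effect sizes cannot be matched to any in-vivo
dataset; the planted delta r = −0.3 is a conventional moderate-to-large
FC difference.

## Known limitations

* Subject-level exclusion only; no volume scrubbing or motion-spike
  interpolation.
* Negative-correlation handling is a policy, not a solved problem; all
  three options ship but only zeroing is tested in depth.
* With 12 nodes, sparsity 0.10 yields 7-edge graphs on which clustering
  is almost always zero and gamma is frequently undefined; the sparsest
  levels are kept for completeness of the sweep, but inference there is
  weak.
* The permutation test assumes exchangeable subjects under the null;
  cohorts with structured confounds (site, sex, day) need a restricted
  permutation scheme that is not implemented.
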