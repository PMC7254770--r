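---
title: "Methods: weighted functional connectome analysis with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted functional connectome analysis with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models and procedures implemented
in **funcnet**, the conventions and defaults they use, what the synthetic
cohort generator does and does not emulate, and the design decisions taken
where the methodology is genuinely underdetermined.

## 1. From time series to networks

A subject is a T × N matrix of regional mean signals (defaults T = 197
volumes at TR = 3 s, N = 90 regions, matching a typical elderly
resting-state acquisition). Construction proceeds in three steps.

**Band-pass filtering.** `bandpass_filter()` applies a zero-phase
(forward–backward) Butterworth filter of order 4 with passband
0.01–0.1 Hz after demeaning each column. The band is the conventional
low-frequency window for resting-state fluctuations; the filter design is
a package choice (only the band is canonical). Forward–backward
application squares the magnitude response, so the empirical gain measured
in the tests is ≥ 0.9 in mid-band (0.05 Hz) and ≤ 0.2 at 0.16 Hz for this
TR. The upper edge must stay below the Nyquist frequency 1/(2·TR).

**Correlation.** `correlation_matrix()` computes the sample Pearson
correlation for every region pair, with two-sided p-values from the t
distribution with T − 2 degrees of freedom. Zero-variance regions are
rejected by name rather than propagated as NaN.

**Thresholding.** `threshold_network()` retains edge (i, j) iff
p_ij < α / n_tests, with α = 0.05 and n_tests fixed at the full pair
count N(N−1)/2 (4005 at N = 90) even if some pairs were untestable — the
denominator is a property of the design, not of the data. Retained
correlations become weights under a configurable negative-edge policy:

* `"positive"` (default) — only positive significant correlations are
  kept. The path and clustering metrics below assume nonnegative weights,
  and at the Bonferroni level with ~200 time points negative correlations
  of passing magnitude are rare after global-signal-free preprocessing.
* `"absolute"` — weight = |r|, for users who regard anticorrelation
  magnitude as connectivity.
* `"keep-signed"` — weights keep their sign; the topological stages then
  refuse the network explicitly rather than silently producing
  geometry-free numbers.

The ambiguity is real (thresholding literature is silent more often than
not), so all three policies are first-class and recorded in the network's
provenance.

## 2. Topological metrics

All metrics operate on edge lengths 1/w — a stronger correlation is a
shorter functional distance. Conventions, fixed package-wide:

* **Weighted clustering** uses the geometric-mean-of-triangle-weights
  form with weights rescaled by the network maximum, bounded in [0, 1].
* **Disconnected pairs** contribute 0 to efficiencies (1/∞); nodal and
  global shortest path length average *finite* distances only, and the
  number of unreachable pairs is reported alongside rather than folded
  into the mean. Efficiency-type measures are preferred for disconnected
  networks precisely because they need no such convention.
* **Isolated nodes** have strength, clustering and both efficiencies 0,
  and missing path length.
* **Network strength** summarizes nodal strengths by their mean
  (configurable to sum); the mean keeps the quantity on the scale of a
  nodal strength and is consistent with typical reported magnitudes.
* **Hierarchy** is β in c ∝ k^−β, estimated as the negated slope of the
  log c on log k regression over nodes with k > 1 and c > 0 (the excluded
  count is reported).
* **Assortativity** is the Pearson correlation of endpoint degrees over
  edges (each edge contributing both orientations).
* **Small-worldness** σ = γ/λ with γ = C/⟨C_rand⟩ and λ = L/⟨L_rand⟩ over
  an ensemble of `rewire_null()` networks: Maslov–Sneppen double-edge
  swaps, 10·|E| attempted swaps, weights carried with the rewired edges,
  so both the binary degree sequence and the weight multiset are
  preserved exactly. Default ensemble size 100. Quantities that are
  undefined on a given graph (σ with < 2 edges, degenerate hierarchy
  regressions) are reported as missing, never imputed.

Shortest paths and connected components are delegated to igraph; every
metric is verified against brute-force oracles (exhaustive Floyd–Warshall
relaxation, explicit triple enumeration) to 1e−9 in the test suite.

## 3. Rich club, hubs, and connection distance

The weighted rich-club coefficient at degree level k is the total weight
among nodes of degree > k divided by the sum of the equally many strongest
weights anywhere in the network; the normalized curve divides by the mean
over rewired nulls. Levels with fewer than two qualifying nodes, or a
club with no internal edges, are stored as missing — a zero would corrupt
normalized curves.

Hubs are the top ceil(fraction · N) regions (fraction 0.15 by default:
14 of 90; 0.10 and 0.20 give 9 and 18 for sensitivity analyses) ranked by
mean nodal *degree* across all subjects of both groups pooled. Degree
ranking is the default reading of "highest nodal degree"; strength
ranking is available because the underlying network is weighted and the
choice is not universal. Ties at the selection boundary are all included
and the inflation recorded — deterministic and auditable, at the price
that tied data can return more than the nominal count. Edges are then
classed rich-club / feeder / local by how many endpoints are hubs, with
per-class strength (Σw), degree (count) and average strength.

Connection distance is the Euclidean distance between region centroids.
The range [d_min, d_max] over all pairs is cut into three equal-width
bins; the classical extremes 7.61 and 150.98 mm give boundaries 55.40 and
103.19 mm. The bundled 90-region atlas carries **synthetic** centroid
coordinates (mirror-symmetric, realistically spaced); it exists so the
package is self-contained, and any real atlas table (label, x, y, z) can
be substituted.

## 4. Group inference

Global metrics and connection-class summaries are compared by two-sample
t-tests, pooled variance by default (Welch optional), uncorrected. Nodal
metrics are compared per region with Benjamini–Hochberg FDR control at
q = 0.05 *within each metric family* (the N regional tests of one
metric form one family). Metric–covariate associations are
pairwise-complete Pearson correlations; subjects missing a covariate
simply drop out of that pair's n, which reproduces biomarker-subsample
analyses without special handling.

**Network-based statistic.** Edgewise two-sample t-tests on weights
(absent edges are zeros; by default an edge is tested if present in at
least one subject), a primary uncorrected threshold (default p < 0.001),
connected components of the suprathreshold graph, and a permutation null
of the maximal component size in links. The corrected p of a component of
size s is (1 + #{null ≥ s}) / (1 + n_perm), with full label permutation
and no stratification. Directionality follows the reporting convention
for hyper- vs hypo-connectivity: two one-sided analyses (A > B, B > A)
at the primary threshold, each with its own null, each controlling its
own family-wise error; a two-sided mode exists. The corrected
significance level is a parameter (default 0.05) separate from the
primary threshold.

A note on calibration: the maximal-component statistic is integer-valued.
When the expected number of suprathreshold edges under the null is ≪ 1,
the null distribution of the maximum collapses onto {0, 1} and the test
becomes strictly conservative — family-wise error far below nominal.
This is an intrinsic property of component-based permutation tests, not
an implementation artefact. The calibration experiment in the test suite
therefore runs in a regime with ~9 expected null suprathreshold edges
(30-node networks, one-sided primary α = 0.02, 20 + 20 subjects, 500
permutations, 200 replicates), where the statistic has enough support for
the measured family-wise error to be informative; there it falls inside
the exact binomial 95% band around 0.05. Power is demonstrated
separately: a 6-node clique planted at +0.3 latent correlation
(30 + 30 subjects) is recovered with median edge-set Jaccard 1.0 over 20
seeds.

## 5. Classification

Features are the fixed-order upper-triangle vectorization of the weight
matrix (N(N−1)/2 connection features) and three nodal blocks (strength,
nodal global efficiency, nodal local efficiency; 3N features). The
classifier is a soft-margin linear SVM (cost C = 1, configurable) on a
convex combination of one linear kernel per feature family,
K = β₁K₁ + β₂K₂. Because the kernels are linear, the combination is
realized exactly by concatenating the per-family z-scored, selected
feature blocks scaled by √βₘ — no dedicated multiple-kernel solver is
needed, and forcing β = (1, 0) reproduces the single-family classifier
bit-for-bit (asserted in the tests). β is chosen on the simplex grid
{0, 0.1, …, 1} by stratified inner k-fold validation (default 5) on the
training subjects of each outer fold.

Evaluation is leave-one-out cross-validation. Feature standardization
and t-test selection (p < 0.001) are computed inside each training fold
by default, so no information from the held-out subject leaks into the
model; a `"pooled"` mode that selects once on the full sample is provided
because published pipelines frequently did exactly that, and the two
modes can be reported side by side. If no feature passes selection, the
single smallest-p feature is kept so every fold yields a prediction (the
fallback is logged). Group B is the positive class; accuracy,
sensitivity and specificity follow the exact confusion-count formulas,
and the ROC is swept over unique decision scores with trapezoid AUC —
equivalent to the rank/concordance statistic with ties counted 1/2.

## 6. The synthetic cohort generator

`generate_cohort()` draws each subject's innovations from a multivariate
normal with a block community correlation matrix: correlation
`base_within_community_corr` (default 0.35) inside a community,
`base_between_community_corr` (default 0.10) between, six communities by
default with an 18-region DMN-like community on the bundled atlas
(medial frontal, cingulate, hippocampal/parahippocampal, precuneus,
angular regions). Group B receives planted increments on designated
edges of the latent correlation (the pipeline default plants increments
from the bilateral parahippocampal regions onto six DMN partners). If
planting breaks positive semi-definiteness, the matrix is projected back
by eigenvalue clipping and renormalized to unit diagonal; the maximum
entry change is recorded, and increments that push any correlation out
of (−1, 1) are rejected naming the edge. Innovations are coloured by a
per-region AR(1) recursion (coefficient 0.3, stationary via a 50-sample
burn-in), which leaves lag-0 cross-correlations equal to the latent ones
while giving the series realistic temporal autocorrelation within the
analysis band.

Covariates use the conditional-normal construction: for a target
correlation ρ with a subject-level nodal metric, the covariate is
ρ·z + √(1−ρ²)·ε against the *realized*, standardized metric of each
in-scope subject, computed through the package's own
correlation–threshold–metric path. This achieves the target correlation
without iterative fitting; recovery within ±0.1 at n = 500 is part of
the acceptance checks (the pipeline default plants an amyloid-like
covariate at ρ = −0.67 against left-parahippocampal strength in group B,
and a memory-like score at ρ = −0.30 in group A).

Default cohort dimensions (64 + 66 subjects, 90 regions, 197 volumes,
TR 3 s) mirror the study design the generator emulates. What the
generator does **not** emulate: voxel-level structure and preprocessing
artefacts, head motion, physiological noise spectra, spatial
autocorrelation of neighbouring regions beyond the community blocks,
site/scanner effects, and the empirical marginal distributions of real
regional signals (variance and autocorrelation are stipulated, not
fitted — the source data's empirical moments are not public). Passing
tests therefore demonstrate correctness and calibration of the
*methods* on data with known structure, not performance claims about any
real population.

## 7. Numerical choices and degenerate inputs

* Correlations are clamped to [−1, 1] before the t transform; |r| = 1
  maps to p = 0.
* Latent Cholesky factorization happens once per group, innovations are
  a single matrix product per subject; generation is a pure function of
  (spec, seed), asserted bit-identical in the tests.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline gives each stage its own seed field.
* Empty graphs: rich-club profile is empty; σ/β/assortativity are NA
  with < 2 edges; a triangle (no degree-preserving swap exists) rewires
  to itself with 0 accepted swaps.
* Permutation p-values use the add-one form, so they are never 0 and
  the test remains valid at any permutation count.
* Tie-breaks: hub boundary ties are included (logged); β grid ties take
  the first grid point; ROC ties are handled by the threshold sweep
  itself.

## 8. Problem sizes used in the validation suite

The test and acceptance runs are scaled to single-CPU desk hardware as a
design choice: oracle comparisons on graphs of ≤ 12 nodes; null-model
bands with 50–100 rewired networks; NBS calibration with 200 replicates
of 20 + 20 subjects at 500 permutations; clique recovery over 20 seeds of
30 + 30 subjects; covariate recovery at n = 500 subjects × 90 regions ×
197 volumes; demo pipeline and classifier runs with 20 + 20 subjects.
Production analyses would typically raise the NBS permutations to 5000
and the null ensembles to a few hundred; nothing else changes.

## 9. Known limitations

* The negative-edge policy, hub-ranking mode and selection placement are
  configurable precisely because the methodology they mirror is
  ambiguous; results can differ across these choices and the provenance
  fields exist to make the choice visible.
* The rich-club normalization inherits the variance of its null
  ensemble; at small ensemble sizes φ_norm is noisy where clubs are
  small.
* The bundled atlas's coordinates are synthetic; distance-stratified
  results on it are structurally meaningful (terciles, symmetry) but not
  anatomically interpretable — supply a real atlas for that.
* LOOCV has high variance at these sample sizes; the chance-band test
  uses 50 label permutations for that reason.
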