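---
title: "Decentralized VBM and dynamic connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decentralized VBM and dynamic connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decentnet)
```

`decentnet` simulates multi-site neuroimaging analyses in which subject-level
data never leaves its site: sites and a distinguished-but-ordinary aggregator
site exchange only aggregate statistics, and every exchange is logged so that
communication can be audited against closed-form predictions. This vignette
records the models, the parameters that matter, the numerical choices, and
what the synthetic tests do and do not establish.

## Decentralized regression

Each site $j$ holds an augmented design $X_j$ (covariates plus a trailing
intercept column) and responses $y_j$ — in the voxelwise setting, one
response column per masked voxel sharing a single design. The global
objective is the plain sum of squared errors
$F(w) = \sum_j \sum_i (y_i - w^\top x_{i,j})^2$, which separates exactly
across sites; its gradient is the sum of local gradients. The package keeps
the sum form (rather than the mean-squared form, which has the same
minimizer) so aggregation is a plain addition.

Three fitting strategies are provided:

* **Single-shot** — one round: each site ships its local least-squares
  solution and sample count; the aggregator takes the sample-size-weighted
  average. Site indicator covariates cannot enter the local designs (within
  a site the indicator is constant, hence collinear with the intercept), so
  single-shot fits a smaller model and its averaged weights are generally
  suboptimal: its per-voxel SSE is bounded below by the pooled SSE, which
  the test suite asserts at every voxel.
* **Normal equation (DRNE)** — one round: sites ship $X_j^\top X_j$ and
  $X_j^\top y_j$; the aggregator solves the summed normal equations. This is
  algebraically the pooled solution, independent of how rows are partitioned;
  tests require agreement with a pooled QR solve to 1e-10 and partition
  invariance at the same tolerance.
* **Multi-shot** — iterative: the aggregator broadcasts $w$, sites return
  local gradients, and the aggregator applies an Adam update to their sum.
  Sites evaluate gradients through cached local moments
  ($2(X_j^\top X_j w - X_j^\top y_j)$), which is algebraically identical to
  re-touching raw rows and lets all voxels advance in one matrix update.

Inference is likewise decentralized. $R^2$ uses the weighted average of
local response means for the global mean, then sums local SSE and SST.
t-values use the standard OLS sampling variance,
$t_m = w_m / \sqrt{\hat\sigma^2\,[(\sum_j X_j^\top X_j)^{-1}]_{mm}}$ with
$\hat\sigma^2 = SSE/(n-d-1)$, two-tailed p-values from the Student-t
distribution, and no multiple-testing correction (maps report raw signed
log-significance, $-\log_{10}(p)\cdot\mathrm{sign}(t)$). When a toy problem
leaves no residual degrees of freedom, inference is reported as `NA` rather
than an error, so exactly determined examples still fit.

### Adam settings and annealing

Defaults: learning rate 0.01, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, stop at aggregated-gradient infinity norm
$\le 10^{-6}$ or weight change $\le 10^{-9}$, cap 10000 iterations, zero
initialization. Adam's per-coordinate scaling is what makes raw covariates
workable here: age (18–65) and binary indicators differ by orders of
magnitude in gradient scale, and plain gradient descent would need
per-column standardization.

One addition was forced by the mathematics: with a constant learning rate,
full-batch Adam on a quadratic does not converge to the optimum — the
iterates enter a limit cycle whose radius is proportional to the rate, and
the gradient norm stalls orders of magnitude above the $10^{-6}$ tolerance.
The optimizer therefore anneals: whenever the gradient norm fails to improve
for 50 consecutive rounds, the rate is halved (`anneal_patience`,
`anneal_factor` in `optimizer_config()`). With the defaults, the standard
3-site problem converges in roughly 4000 rounds; a run that hits the cap is
returned flagged `converged = FALSE`, never silently.

### Voxelwise maps

`run_voxelwise()` shares one design per site across all voxels, computing
each site's Gram matrix once. Voxels whose global response is constant
(zero SST) are flagged with NaN in every output grid instead of aborting;
NaN is also the sentinel for unmasked voxels when mapping statistics back
onto the 3-D grid. Output volumes are written in the input grid's affine;
no resampling is performed.

## Decentralized group spatial ICA

The generative model is linear spatial ICA: each subject's voxels-by-time
block is a mixture $A S$ of $r$ statistically independent spatial maps with
subject-specific time-courses. The pipeline:

1. **Subject PCA** (`local_pca()`): temporal reduction to $k_1$ whitened
   principal directions (unit variance, zero covariance across voxels). A
   full-scale analysis uses $k_1 = 120$; desk-scale tests use 20.
2. **Global PCA** (`global_pca()`): sites chain peer-to-peer; each stacks
   the previous site's $d \times r$ reduced basis with its own block in the
   column dimension and reduces again. Intermediate hops keep the
   spectrum-weighted basis $U_r\,\mathrm{diag}(d_r)$ — a plain orthonormal
   basis would discard the singular-value weighting and degrade the pooled
   approximation — and the final basis is re-orthonormalized, giving $V$
   with $V V^\top = I_r$.
3. **ICA at the aggregator** (`infomax_ica()`): rows of $V$ are centered and
   sphered, then unmixed by natural-gradient infomax with the logistic
   nonlinearity — appropriate for the super-Gaussian (sparse) sources that
   brain maps resemble. Updates run over randomly permuted column blocks of
   size $\max(8, \lfloor\sqrt{d}\rfloor)$; the learning rate (default
   $0.01/\log(r+1)$) is annealed when successive weight updates turn by more
   than 60 degrees; the run stops when a pass changes the weights by less
   than $10^{-7}$. A weight-norm blow-up raises an error naming the pass.
   All randomness sits under one seed, so a fit is exactly reproducible.
4. **Back-reconstruction** (`back_reconstruct()`): subject time-courses from
   a least-squares projection of the subject data onto the group maps, then
   subject maps from a second regression on those time-courses.

The printed relation between the mixing matrix and the unmixed eigenvectors
is dimensionally ambiguous in the source literature; here the estimated
independent spatial maps are the rows of $W V$, stored transposed as the
$d \times r$ matrix `A_hat`. ICA's permutation and sign indeterminacy is
resolved only at comparison time (`match_components()`, Hungarian assignment
under $1 - |\mathrm{cor}|$), never inside the fit.

## Decentralized dynamic connectivity

Per-subject cleaning drops the first 2 timepoints, projects out 24 motion
regressors (6 rigid-body parameters, their first differences, and the
squares of both, plus an intercept), and replaces motion spikes — timepoints
whose framewise displacement strictly exceeds $\mathrm{mean}(FD) + 2.5\,
\mathrm{sd}(FD)$ — with cubic-spline values fitted through the good
timepoints.

Sliding windows are rectangular, stride 1, length $w = 22$ by default, and a
$T$-point series yields $T - w$ windows (so 162 points give exactly 140).
The counting convention deliberately leaves the trailing window unused; the
standard full-scale count of 140 windows arises on the raw 162-point
series, before the 2-point drop. Each window contributes the strict upper
triangle of its sample covariance, vectorized row-wise —
$r(r-1)/2$ features. The constant diagonal position adds nothing under the
correlation distance, so the full $r^2$ payload in the bandwidth formula is
treated as an order-of-magnitude statement and the audit uses the vectorized
size. Exemplar windows are the strict interior local maxima of the
per-window connectivity-variance series (variance across feature entries,
computed on covariance rather than correlation entries); a monotone or
constant series falls back to the single global-maximum window.

`dkmeans()` alternates local assignment under the correlation distance with
count-weighted centroid merging at the aggregator, stopping when assignments
survive a full round unchanged (cap 1000). Centroids are arithmetic means of
assigned feature vectors. With one site this is exactly Lloyd's algorithm,
which the tests check against `stats::kmeans`. An empty cluster is reseeded
from the globally farthest point (largest distance to its assigned
centroid), at the cost of one extra logged upload. Ties in assignment break
toward the lowest centroid index.

`run_ddfnc()` runs the two-stage procedure: 200 (default) seeded
initializations on the exemplars, centroids drawn uniformly from the
exemplar windows, each run scored by the mean silhouette width on the
exemplars under the same correlation distance; the winner initializes a
final clustering over all windows. A master seed derives one child seed per
initialization, so the whole procedure is reproducible.

## Message accounting

Every protocol threads a `message_log()`; payload sizes count real scalars
(matrix dimensions), not bytes, and integer sample/cluster counts ride along
untallied. Conventions worth stating:

* dgICA: a chain-head site sends one $d \times r$ hop and receives the
  $r \times r$ unmixing matrix, totalling $dr + r^2$ — the audited figure.
  The aggregator's printed total $dr + r^2 s$ counts a broadcast to all $s$
  sites; the simulator delivers to the $s-1$ other sites, so its logged
  total is smaller by one $r^2$ payload.
* Multi-shot regression: the intercept slot is counted in both directions,
  $d+1$ scalars per site per round each way (per voxel).
* DRNE: one Gram matrix plus one moment vector per site —
  $(d+1)^2 + (d+1)$ scalars for a single response.

## The synthetic generators

`gen_multisite_regression()` emulates a multi-site VBM covariate structure:
age uniform on 18–65, diagnosis and gender Bernoulli(0.5), additive per-site
offsets (evenly spread over ±0.5), Gaussian voxel noise (sd 1), and known
per-voxel coefficients. Defaults: 3 sites × 50 subjects, 200 voxels.

`gen_fmri_subjects()` emulates the dynamic-connectivity structure: $r$
spatial sources as Gaussian blobs on a 3-D grid (sparse, hence
super-Gaussian across voxels), $k$ correlation-scaled covariance templates
kept pairwise at correlation distance ≥ 0.5, per-subject state sequences
with dwell lengths drawn uniformly between one and two window lengths,
component time-courses sampled i.i.d. within a segment from the active
template, voxel noise (sd 0.1 against unit-scale sources), random-walk
motion parameters, and an FD series with spikes of ten times the 0.1
baseline planted at known indices. Defaults: 2 sites × 10 subjects each,
500 voxels (10 × 10 × 5), $r = 5$, $k = 3$, $T = 162$ — sized so the full
suite runs in well under a minute while keeping the structure of a
full-scale study (314 subjects, $k = 5$, 100 components).

What the generators do *not* emulate: spatial autocorrelation of noise,
hemodynamics, scanner- or site-specific artifacts beyond an additive offset,
realistic covariate-effect sizes, or registration/segmentation error.
Passing tests therefore establish algorithmic correctness — decentralized
equals pooled, planted structure is recovered — not robustness to real
acquisition variability.

### Scoring state recovery

Fitted centroids are Hungarian-matched to the planted templates, and label
accuracy is evaluated over *pure* windows only — windows whose timepoints
all lie in one dwell segment. A window straddling a transition has a
covariance that mixes two templates and no well-defined true label; with
dwell lengths between $w$ and $2w$, roughly half the windows straddle, which
would bound any method's apparent accuracy regardless of quality. Pure-window
accuracy on the default generator exceeds 0.9; centroid-template correlations
exceed 0.95.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use the generator defaults above:
150 subjects × 200 voxels for regression comparisons (a few seconds,
including the ~4000 multi-shot rounds) and 10–20 subjects × 500 voxels for
the ICA and clustering pipelines (tens of seconds, dominated by the 200
K-Means initializations). Every stochastic component — generators, ICA,
K-Means initializations — draws from explicit seeds, and identical seeds
reproduce results bit-for-bit.

## Known limitations

* The simulator exchanges no real network traffic: no encryption,
  differential privacy, fault tolerance, or asynchronous updates. Rounds
  are synchronous by construction.
* Single-shot inference computes global t-values from the averaged weights
  via the decentralized variance formula; classical meta-analytic pooling of
  per-site t-statistics is a documented alternative, not implemented.
* Regularized variants (ridge/lasso/elastic-net), interaction terms,
  graphical-LASSO covariance estimation, Fisher-Z transforms, static-FNC
  regularization and data-driven selection of the cluster count or component
  count are all out of scope.
* The peer-to-peer global PCA is order-dependent in principle; with the
  rank-$r$ spectrum-weighted hops used here the desk-scale decentralized
  subspace matches the pooled one to high correlation, but exact equality is
  only guaranteed for a single site.
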