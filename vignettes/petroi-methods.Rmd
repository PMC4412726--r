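---
title: "Methods: mixture-based ROI discovery for FDG-PET classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-based ROI discovery for FDG-PET classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petroi)
```

## Overview

`petroi` discovers regions of interest (ROIs) in spatially normalized
FDG-PET volumes by clustering a reference image, then uses those ROIs as
feature extractors for classifying diagnostic groups (normal controls,
mild cognitive impairment, Alzheimer's disease). This vignette is the
package's own account of the model, its assumptions, the tunable
parameters, and the numerical and design choices — including what the
synthetic phantom does and does not demonstrate.

## The model

### Gaussian mixtures on voxel coordinates

A voxel is a 4-tuple $(x, y, z, I)$: three spatial coordinates and a
relative-uptake intensity. The discovery step first groups the masked
voxels of the reference image into $B$ equal-width intensity bins, so
voxels within a bin are metabolically similar; each bin is then clustered
*spatially* with a $K$-component Gaussian mixture

$$p(\mathbf{s} \mid \theta) = \sum_{k=1}^{K} \pi_k\,
  \mathcal{N}(\mathbf{s} \mid \mu_k, \Sigma_k), \qquad
  \mathbf{s} = (x, y, z),$$

fitted by EM with full covariances. The resulting clusters are
intensity-homogeneous by construction (the bin width bounds the
within-cluster intensity spread) and geometrically compact (the spatial
fit). Assumptions worth stating: voxel coordinates are treated as
unitless grid indices, appropriate after spatial normalization onto an
isotropic template grid; clustering on physical millimetre coordinates
would differ only by a fixed scaling per axis and was not pursued.
Coordinates are 1-based, following R's array convention.

### Choosing the number of components

$K$ is chosen per bin by an information criterion,
$\mathrm{BIC} = -2\log L + P\log N$ (default) or
$\mathrm{AIC} = -2\log L + 2P$, where
$P = K D (D + 3)/2 + K - 1$ counts the free parameters
($K-1$ proportions, $KD$ means, $KD(D+1)/2$ covariance entries) and $N$
is the number of voxels in the bin. Lower is better; ties break toward
smaller $K$ for determinism. Differences between BIC scores can be
graded on the conventional Bayes-factor scale (`grade_evidence()`:
0–2 weak, 2–6 positive, 6–10 strong, >10 very strong).

The candidate range of $K$ encodes a cluster-size prior: clusters should
hold at most 1000 and at least 30 voxels, so a bin of $N$ voxels scans
$K \in [\lceil N/1000 \rceil, \lfloor N/30 \rfloor]$ (floored at 1; a
degenerate range makes the bin a single cluster). These bounds act only
through the search range — no post-hoc splitting or merging of components
is applied. Every integer $K$ in the range is scanned by default; a
stride is configurable for very wide ranges.

### Numerical choices

* **Log-space likelihoods.** Component log-densities come from a
  Cholesky factorization, and mixture log-likelihoods use the
  log-sum-exp trick with the largest weighted component factored out.
  The likelihood therefore matches direct summation to ~1e-10 relative
  where the direct path is representable, and remains finite on data
  scaled by factors like $10^{\pm 150}$ where it is not.
* **Initialization.** Farthest-point seeding of means from the data
  (first centre random, subsequent centres maximizing the minimum
  distance), a small jitter (1% of the per-axis SD), then one hard
  assignment pass. Three independently seeded restarts by default; the
  restart with the best final log-likelihood wins. All randomness flows
  through one explicit seed and the caller's RNG state is restored.
* **Regularization.** $\varepsilon I$ with
  $\varepsilon = 10^{-6} \times$ mean marginal data variance is added to
  every covariance update, which keeps one-voxel-thick slabs of lattice
  coordinates positive definite. The ridge is small enough that the EM
  trajectory stays non-decreasing within 1e-8, which the tests assert
  over 100 seeded instances.
* **Convergence.** $|\Delta \log L| < 10^{-6}$ (absolute), at most 300
  iterations. On lattice data with overlapping components EM often uses
  the full budget; the trajectory is returned so users can inspect it.
* **Degeneracy.** A component whose total responsibility falls below
  1e-12 aborts the restart; if all restarts fail, that $K$ is skipped
  with a warning, and a bin whose every $K$ fails collapses to a single
  cluster.
* **Tie-breaking.** Smaller $K$ in model selection, lowest component
  index in hard assignment, fewest bins in the inner bin selection,
  smallest penalty in the SVM cost search — all argmin/argmax operations
  resolve ties deterministically toward the first candidate.
* The EM iteration loop is compiled (RcppArmadillo) for speed; it applies
  the same updates as the exported `e_step()`/`m_step()`, and the tests
  verify the two paths agree.

## From clusters to classification

Each subject volume is summarized per cluster by the mean and the sample
standard deviation ($n-1$ denominator; 0 for singleton clusters — the
denominator choice is immaterial at the enforced cluster sizes but fixed
for reproducibility). Features are ranked on training rows by the
absolute pooled-variance $t$ statistic (an entropy-based
information-gain score is available; the ranking method is recorded in
the result). The top 150 features are kept for BIC-selected clusters and
400 for AIC-selected ones, reflecting that AIC prefers more, smaller
clusters and spreads the discriminative signal across more features.

The classifier is a linear soft-margin SVM (libsvm via `e1071`). The
penalty grid defaults to $C \in \{2^{-5}, 2^{-3}, \ldots, 2^{5}\}$,
selected by stratified cross-validation within the training rows.
Prediction scores for ROC pooling are signed decision values: libsvm's
probability calibration shuffles internally in a way that cannot be
seeded from R, and AUC is invariant to any monotone transform of the
scores, so decision values give identical AUCs deterministically. The
score type is recorded in the evaluation settings.

### Cross-validation protocol

The outer loop is stratified 10×10-fold cross-validation: per repeat,
each class is shuffled and dealt round-robin so per-class fold sizes
differ by at most one (30+30 subjects give 3+3 per fold and 54 training
subjects). Within each fold, the bin count $B$ is chosen on a single
stratified 80/20 sub-split of the training subjects — the same split for
every candidate $B$, so candidates are compared on identical data — and
the winning granularity is refitted on the full training rows.
Accuracy, sensitivity (true-positive rate on the disease class) and
specificity are aggregated by instance within each repeat and then
averaged over repeats, which is well defined even when folds hold very
few subjects; AUC is computed once from the scores pooled over all
repeats and folds (Mann–Whitney statistic, ties counted one half).

The positive class for sensitivity is the more impaired group (AD in
MCI-vs-AD), configurable via `positive=`.

Two evaluations sharing a CV plan are compared with the corrected
resampled paired $t$-test,
$t = \bar d \big/ \sqrt{(1/R + n_{\mathrm{test}}/n_{\mathrm{train}})\,
s_d^2}$ on $R-1$ degrees of freedom, which inflates the classical paired
test's variance for the overlap of training sets across runs.

### Leakage control

Cluster discovery runs on the mean normal-control image. When the NC
group is not itself being classified, that reference is independent of
the cross-validated subjects and the cluster maps are computed once and
reused across folds. When the reference group *is* one of the classified
groups, the reference mean — and everything downstream — is recomputed
per fold from training subjects only. Feature ranking, bin selection and
cost selection always see training rows only; the tests assert that
mutating held-out volumes changes neither the ranking, the chosen bins,
the chosen cost, nor the fitted weights.

### Informative-regions report

The regional summary assigns, in every fold, 10 down to 1 points to the
ten clusters whose best-ranked feature appears earliest in the ranking —
a linear scheme, chosen as the simplest monotone scoring of ranking
positions. Points are summed over all folds,
the overall top-ten clusters pooled, and their voxels attributed to
atlas regions; regions are reported by their percentage share of the
pooled voxels, so shares sum to at most 100%.

The weighted-distance diagnostic (`dissimilarity_ratio()`) re-weights
feature rows by the SVM weight vector and reports
$\rho = (D_a - D_b)/D_b$ from the mean Euclidean distances of one test
subject to the two training groups; larger $\rho$ means more similar to
group $b$.

## The phantom

The synthetic generator emulates the data regime the method targets: an
ellipsoidal "brain" partitioned into contiguous regions by a seeded
Voronoi tessellation of random interior sites (irregular, size-varied
regions, as in a real atlas), a constant baseline relative uptake per
region drawn from [0.7, 1.3], group-specific fractional hypometabolism
planted in a chosen subset of regions, i.i.d. Gaussian voxel noise with
SD proportional to the local baseline, and an optional Gaussian blur
that induces the spatial correlation real smoothing produces.

Defaults encode the validation conditions used throughout the tests and
the acceptance script: a 20×24×20 grid (~2700 brain voxels), 12 regions,
2 affected regions, effects of −7% (MCI-like) and −15% (AD-like), noise
SD 10% of baseline, no blur, 20 subjects per group, and an inner bin
grid of {6, 10, 14}. These sizes scale the published workflow down to
desk scale — the bin grid is chosen so bins still hold enough voxels to
support several admissible clusters on the small grid, the same regime
the 50–150 grid occupies on a full 91×109×91 volume, where discovery
alone is reported to take hours. With these settings the planted
MCI-vs-AD contrast (an 8-percentage-point uptake gap against a
region-mean standard error of well under 1%) is strongly separable, so
the pipeline attains accuracy near 1 and the label-permuted control sits
near 0.5.

What passing on the phantom does **not** show: robustness to scanner
effects, partial-volume and point-spread physics, anatomical variability
after imperfect spatial normalization, non-constant within-region
baselines, or overlapping group distributions of realistic effect size.
The phantom validates the machinery (partitioning, selection,
no-leakage, calibration at chance), not clinical performance.

## Known limitations

* Pairwise contrasts only; no three-way classification and no
  MCI-progression modelling.
* Spatial normalization and smoothing are assumed done upstream; the
  package consumes already-normalized grids and applies no world-space
  transform.
* Mixture variants (diagonal/tied covariances, Bayesian mixtures) and
  spatially regularized clustering are out of scope.
* The informative-regions report requires the shared-reference
  evaluation path, where cluster maps are retained.
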