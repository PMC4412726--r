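# petroi

Data-driven discovery of discriminative metabolic brain regions in
FDG-PET volumes, and their use as classification features for dementia
diagnosis (NC / MCI / AD contrasts).

## The problem

FDG-PET voxel intensities reflect regional glucose metabolism;
Alzheimer's disease shows up as regional hypometabolism. Classification
pipelines need per-subject features, and the classical choices are either
purely anatomical (mean/SD of intensity over the regions of a brain atlas
such as AAL) or mass-univariate (a voxel-wise t-test keeping the most
significant voxels). The first ignores the data; the second ignores
spatial correlation between voxels.

`petroi` implements a semi-data-driven middle ground: regions of interest
are *learned* from a reference image by a two-phase clustering, then used
as feature extractors for every subject.

## The method

1. **Intensity binning.** The masked voxels of a reference image (the
   voxel-wise mean of the normal-control scans) are divided into `B`
   equal-width intensity bins, so each bin holds voxels of similar
   relative uptake.
2. **Spatial mixture clustering per bin.** Inside each bin, a Gaussian
   mixture model is fitted to the voxel coordinates `(x, y, z)` by EM.
   The number of components `K` is chosen by BIC (or AIC),

   `BIC = -2 log L + log(N) P`,  `AIC = -2 log L + 2 P`,

   with `P = K·D(D+3)/2 + K - 1` free parameters, scanning the interval
   of `K` for which clusters hold between 30 and 1000 voxels. The
   log-likelihood is evaluated with the log-sum-exp trick so fits stay
   finite at any intensity scale.
3. **Features.** Each subject volume is summarized by the mean and
   standard deviation of its intensities over every discovered cluster
   (M clusters → 2M features; e.g. 1000 clusters → a 2000-vector).
4. **Evaluation.** A linear SVM inside repeated stratified 10×10-fold
   cross-validation, with the bin count `B` chosen on an inner
   sub-training/sub-test split, features ranked (|t|-statistic) on
   training rows only, the SVM penalty `C` grid-searched on the training
   data, and metrics aggregated by instance per repeat and then averaged.
   ROC curves pool the predicted scores over all test folds; methods are
   compared with the corrected resampled paired t-test.

Baselines: atlas region features (116 AAL regions → 232 features) and
voxel-wise two-tailed t-test selection (p < 0.001, top-150 voxels).
A seeded phantom generator (ellipsoidal brain, Voronoi regions, planted
regional hypometabolism, proportional Gaussian noise) makes the whole
workflow testable without patient data.

## Worked example

```r
library(petroi)

spec <- phantom_spec(seed = 1)          # 12 regions, 2 affected, noise 10%
coh  <- simulate_cohort(spec, c(NC = 10, MCI = 10, AD = 10))
coh
#> Phantom cohort: AD=10, MCI=10, NC=10 (20x24x20 grid, 12 regions,
#>                 affected: Region_04, Region_12)

ref <- mean_reference_image(coh$volumes[coh$labels == "NC"])
map <- discover_clusters(ref, coh$mask, 10, seed = 1)
map
#> Cluster map: 67 clusters from 10 intensity bins (BIC, seed 1)
#>   2728 voxels, cluster sizes 2..150 (median 38)

ev <- evaluate_cohort(coh$volumes, coh$labels, c("MCI", "AD"), coh$mask,
                      cluster_maps = list(map),
                      n_repeats = 2, n_folds = 5, seed = 1)
ev
#> PET cohort evaluation: MCI vs AD, method 'gmm' (BIC)
#>   2 x 5-fold stratified CV, seed 1
#>   Accuracy 100.0%  AUC 1.00  Sensitivity 1.00  Specificity 1.00 (positive: AD)

informative_regions_report(ev, coh$atlas)
#>      region code voxels    percent
#> 1 Region_04    4    360 56.0747664
#> 2 Region_12   12    159 24.7663551
#> 3 Region_08    8     81 12.6168224
#> ...
```

The planted -7% (MCI) vs -15% (AD) hypometabolism in `Region_04` and
`Region_12` is large relative to the region-mean sampling noise, so the
contrast is cleanly separable, and the two affected regions head the
informative-regions report: the discovered clusters concentrate exactly
where the signal was planted.

For real data, `read_volume()` / `read_atlas()` load spatially normalized
NIfTI volumes and an atlas (label volume + `code<TAB>name` table);
`grand_mean_normalize()` or `psmc_normalize()` apply the two intensity
normalizations; `evaluate_cohort(..., method = "atlas")` and
`method = "ttest"` run the baselines on the same CV plan, and
`compare_evaluations()` tests the difference. A thin command-line front
end lives at `inst/cli/petroi.R`.

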