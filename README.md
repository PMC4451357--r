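# eigenbrain

Computer-aided detection of Alzheimer's disease (AD) versus normal elderly
controls (NC) from co-registered 3D structural brain MRI, built around the
*eigenbrain* idea: treat each subject's brain slice like an eigenface problem,
decompose the across-subject variation into orthogonal basis images, and use
the statistically discriminant component both to classify subjects and to
localize the voxels that drive the separation.

The package is aimed at researchers who have a set of spatially normalized,
brain-masked volumes in a common voxel grid (e.g. Talairach space) with a
binary clinical label per subject (CDR 0 = NC, CDR 1 = AD), and at method
developers who want a fully synthetic, ground-truth-equipped testbed for this
family of pipelines.

## The method

For coronal slice index $k$, the **inter-class variance** is

$$v(k) = \lVert \mu_{AD}(k) - \mu_{NC}(k) \rVert^2,$$

the squared Euclidean norm of the difference between the class-mean images.
**Key slices** are those with $v(k) \ge 0.5\,\max_k v(k)$, kept every 10
slices. Per key slice, the $N$ subject images are vectorized into an
$N \times A$ matrix, standardized per voxel, and decomposed by PCA using the
small-sample trick: the $N \times N$ matrix $C' = ZZ^\top/(N-1)$ shares its
nonzero eigenvalues with the $A \times A$ covariance $Z^\top Z/(N-1)$, so at
most $N-1$ **eigenbrains** exist (125 for a 126-subject cohort). Each
subject's projection score on each eigenbrain is compared between classes by
**Welch's t-test**; the **most important eigenbrain (MIE)** is the smallest
index with $p < 0.05$ on every key slice — in the reference cohort this is
always the first eigenbrain, giving 10 features per subject (one per key
slice). A soft-margin SVM (linear, RBF $\exp(-\lVert x-y\rVert^2/\sigma^2)$,
or polynomial $(x^\top y + c)^d$ kernel) is trained by sequential minimal
optimization, optionally tuned by particle swarm optimization, and scored by
repeated stratified 10-fold cross-validation (accuracy, sensitivity,
specificity, precision; AD is the positive class). Finally, pixels of the
MIE whose absolute loading exceeds the 0.98 quantile are flagged as
**discriminant voxels** and can be aggregated against any integer label
volume (atlas stand-in).

A bundled phantom generator produces registered brain-like volumes
(ellipsoidal brain, bright cortical shell, dark ventricle cavity) with
additive AD-specific mean shifts in configurable spherical regions and a
ground-truth effect mask, so the whole pipeline is testable end to end
without external data.

## Worked example

```r
library(eigenbrain)
ph  <- generate_phantom(phantom_config(shape = c(32, 32, 32),
                                       n_nc = 20, n_ad = 10,
                                       noise_sd = 4, seed = 42))
res <- run_pipeline(ph$data,
                    pipeline_config(icv_undersample = 5L, k = 5L,
                                    reps = 10L, seed = 1L))
print(res)
#> pipeline_result
#>   key slices : 15, 20
#>   MIE index  : 1
#> cv_report: 10 x 5-fold CV, pol kernel (tune = none)
#>   accuracy     100.00 +/- 0.00 %
#>   sensitivity  100.00 +/- 0.00 %
#>   specificity  100.00 +/- 0.00 %
#>   precision    100.00 +/- 0.00 %
#> region_map: MIE 1, quantile 0.980, 2 key slices, 42 voxels highlighted

overlap_score(res$region_map, ph$truth, axis = 2)[c("recall", "dice")]
#> $recall [1] 0.5454545
#> $dice   [1] 0.7058824
```

Two coronal slices pass the 50%-of-max rule (the injected effect spans a
narrow band of the small phantom); the first eigenbrain separates the
classes on both (Welch $p < 10^{-13}$), the 2-feature polynomial-kernel SVM
classifies the strongly contrasted phantom perfectly, and quantile
thresholding recovers 55% of the true effect voxels lying in the examined
slices with no false positives. On real cohorts the published workflow
reports accuracies in the low 90s; those numbers require the original
126-subject OASIS-derived dataset and are not asserted here.

The per-slice, per-eigenbrain group summaries of that reference cohort are
bundled (`reference_wtt_summary()`); recomputing Welch's tests from them
singles out eigenbrain 1 on all 10 key slices (60–150, step 10):

```r
sel <- select_mie_from_summary(reference_wtt_summary())
sel$mie_index        #> 1
```

## Command line

```sh
Rscript inst/cli/eigenbrain-cli simulate --out cohort/ --shape 64,64,64 --seed 1
Rscript inst/cli/eigenbrain-cli run --volumes cohort/ --out results/ \
    --kernel pol --folds 10 --reps 50 --seed 1
```

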