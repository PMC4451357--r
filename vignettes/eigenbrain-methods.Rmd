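---
title: "Eigenbrain pipeline: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenbrain pipeline: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenbrain)
```

## The model

The pipeline assumes its input volumes are already motion-corrected,
co-registered to a common space and brain-masked, so that a given voxel
index addresses comparable anatomy across subjects; it performs no
registration or segmentation of its own. Diagnosis is binary: CDR 0 (normal
elderly control, label 0) versus CDR 1 (Alzheimer's disease, label 1).
Intermediate CDR values are rejected at ingestion rather than silently
binned, because the contrast being modeled — class-conditional mean
intensity differences — is not defined for a third group.

**Key-slice selection.** Coronal slices are scored by inter-class variance,
the squared Euclidean norm of the difference between class-mean images. The
coronal direction is used because a single coronal plane can cut cortex,
ventricles and hippocampus at once — the three structures whose atrophy and
enlargement characterize AD. Slices at or above 50% of the maximum score
are candidates; every 10th candidate is kept.

**Eigenbrains.** Per key slice, each subject's H×W image is vectorized
(A = H·W attributes; a 256×256 slice gives A = 65536) and the N×A matrix is
standardized per voxel across subjects (sample SD, denominator N−1;
zero-variance voxels such as masked background become zero columns and are
flagged). PCA is computed via the small-sample trick — eigendecomposition
of the N×N matrix ZZᵀ/(N−1) instead of the A×A covariance — which is exact
for the nonzero spectrum and reduces the cost from O(A³) to O(N³) + one
back-projection. Standardized columns sum to zero, so at most N−1
components survive; with 126 subjects that is 125 eigenbrains, which the
test suite asserts.

**MIE and features.** For each key slice and each of the first `max_rank`
(default 6) eigenbrains, the per-subject projection scores of the two
classes are compared by Welch's unequal-variance t-test
(Welch–Satterthwaite degrees of freedom, two-sided, α = 0.05). The most
important eigenbrain is the smallest index significant on *every* key
slice; its per-slice scores are the classifier features (10 key slices →
10 features per subject). Requiring significance on all slices is a strong
conjunction; the bundled reference summaries show it singles out the first
eigenbrain, and with no class contrast present the selection fails loudly
(a typed error carrying the full test table) rather than returning an
arbitrary component.

**Classification.** A soft-margin SVM with linear, RBF or polynomial
kernel, trained by SMO on the dual, is evaluated by repeated stratified
k-fold cross-validation (default 10-fold, 50 repetitions). AD is the
positive class. Per repetition, fold confusion counts are summed and the
four metrics (accuracy, sensitivity, specificity, precision) computed;
means and SDs are taken across repetitions.

**Region detection.** The MIE's loadings carry arbitrary sign, so the
absolute value is taken; pixels strictly above the 0.98 quantile of
|loading| are flagged as discriminant, per slice, and can be aggregated
against any integer label volume standing in for an anatomical atlas.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `icv_fraction` | 0.5 | fraction of max ICV | candidate threshold |
| `icv_undersample` | 10 | slices | stride between kept key slices |
| `icv_norm` | `squared` | — | see numerical choices |
| `standardize_axis` | `voxel` | — | eigenface convention |
| `max_rank` | 6 | eigenbrains | how many leading components are tested |
| `alpha` | 0.05 | — | the 95% confidence level; no multiplicity correction by default (a Bonferroni switch exists) |
| `C` | 1 | — | soft-margin penalty |
| `sigma` | 1 | feature units | RBF scale, kernel `exp(-‖x−y‖²/σ²)` |
| `degree`, `offset` | 3, 1 | — | polynomial kernel `(xᵀy + c)^d` |
| `k`, `reps` | 10, 50 | folds, repetitions | CV design |
| `quantile` | 0.98 | — | region-detection threshold (top ≈ 2%) |
| PSO | swarm 20, 50 iterations, w = 0.729, c1 = c2 = 1.49445 | — | Clerc constriction values; search bounds C ∈ [2⁻⁵, 2¹⁵], σ ∈ [2⁻¹⁵, 2³] (log₂ scale), c ∈ [0, 10], d ∈ {2..5} (rounded) |

## The phantom: what it emulates, what it does not

The generator states a fixed world: a shared template (ellipsoid "brain" of
tissue intensity 100, bright shell 130 as a cortex analog, dark interior
cavity 30 as a ventricle analog, background 0), i.i.d. Gaussian voxel noise
(default SD 5), class sizes defaulting to the reference cohort's 98 NC / 28
AD, and additive mean shifts applied to the AD class only inside three
spherical regions (cortex-shell patch −25, periventricular −35,
hippocampus-analog −30 intensity units). The magnitudes were chosen once to
satisfy "strong effect, magnitude ≫ noise" — about 5–7 noise SDs — and are
not adjusted to test outcomes. The ground-truth mask is exactly the set of
voxels with nonzero expected class contrast.

Deliberately *not* modeled: anatomical realism, spatially correlated noise,
bias fields, registration error, partial-volume effects, or within-class
heterogeneity. A green end-to-end test therefore establishes that the
implementation correctly recovers a strong, additive, spatially compact
contrast under independent noise — not that the method attains any
particular accuracy on real MRI, where the published reference numbers
(accuracy in the low 90s) depend on the original OASIS-derived cohort and
are excluded as numeric targets here.

## Numerical and design choices

- **Squared vs plain norm in the slice score.** The defining notation
  (‖·‖² glossed as "the l2-norm") is ambiguous. The squared norm is the
  default, as printed; since the 50%-of-max rule is sensitive to the
  choice, `icv_norm = "plain"` is an explicit switch rather than a silent
  interpretation.
- **Undersampling anchor.** The stride is anchored at the smallest
  candidate index (deterministic; reproduces an every-10 pattern on a
  contiguous candidate run). Stride offsets are counted in slice indices,
  not candidate ranks, so gaps in the candidate set do not shift the
  phase. For contiguous runs, thresholding before or after undersampling
  gives the same result under this anchoring.
- **Per-voxel standardization.** The source wording ("each sample …
  subtracting its mean") reads per-sample, but the covariance being
  decomposed is across voxels and the eigenface lineage standardizes per
  attribute; per-voxel is the default with `standardize_axis = "sample"`
  as an escape hatch.
- **Eigenvector sign.** Flipped so the largest-magnitude loading is
  positive. This makes decomposition bit-stable; the Welch test
  (two-sided) and region detection (absolute value) are sign-invariant, so
  the convention affects no scientific output.
- **Rank tolerance.** Eigenvalues below 1e−10 × the leading eigenvalue are
  numerical noise and dropped.
- **PCA on all subjects.** The basis is fit on both classes pooled, before
  any CV split, matching the reference workflow; the score features
  therefore carry a (documented) mild information leak into CV. Refitting
  per fold would change the feature space per fold and is out of scope.
- **RBF denominator.** `exp(-‖x−y‖²/σ²)` exactly as printed — not the also
  common `2σ²`. Only the parameterization of σ differs, not the model
  family.
- **Stratified folds.** The reference describes plain random folds; with
  28 positives among 126 subjects a 10-fold random split can lose the AD
  class from a training fold entirely, so folds are stratified by class — a
  deviation by necessity.
- **Feature scaling in CV.** Features are standardized by training-fold
  mean/SD inside every fold (SVMs are scale-sensitive; the source is
  silent on this).
- **Tuning default.** `cross_validate(tune = "none")` uses the supplied
  kernel spec. `tune = "once"` (PSO on the full data set, then CV) is the
  closest reading of the reference workflow but lets tuning see test
  folds; `tune = "nested"` re-tunes inside every training fold and is
  leakage-free but costs two extra orders of magnitude of SVM fits, which
  is why it is not the default despite being methodologically cleanest.
  All three are implemented and tested.
- **Quantile details.** Linear interpolation between order statistics
  (type 7, the common default), strict inequality at the threshold (an
  all-constant image highlights nothing), computed per key slice (the
  per-slice workflow of the reference) over all pixels of the eigenbrain
  image by default — background loadings are near zero and fall below any
  high quantile — with an optional mask to restrict the population.
- **MIE tie-break.** If several indices pass on all slices, the smallest
  wins: earlier components carry more variance.
- **Welch testing scope.** The first `max_rank` eigenbrains are both
  displayed and eligible for selection; whether the reference restricted
  testing to six only for display is unknowable from the text, so the
  bound is configurable.
- **CDR handling.** Only 0 and 1 are accepted; anything else is rejected
  with the offending subjects listed.

## Known limitations

- The NIfTI layer is minimal by design: uncompressed single-file `.nii`,
  common datatypes, no qform/sform interpretation — the coronal axis must
  be declared, not inferred. Compressed or oblique real-world data should
  be converted upstream.
- Pure-R SMO is adequate for the ~10-feature, ~126-subject problems this
  pipeline produces; it is not a general-purpose SVM for large N.
- The permutation-null behavior (accuracy ≈ majority rate, 98/126 ≈ 77.8%)
  is asserted under the phantom's imbalance; heavily balanced designs will
  sit near 50% instead.
- Eigenbrains are two-dimensional: redundancy along the slice axis is
  reduced only by the 10× undersampling, not modeled.
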