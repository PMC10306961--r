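---
title: "Radiomic texture, fractal dimensions and TNR: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture, fractal dimensions and TNR: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(petrad)
```

This vignette is the package's own account of its science: what each stage
models, which tunable parameters matter, what the synthetic data does and
does not establish, and where a genuinely open design choice was resolved.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## The pipeline in one paragraph

A case is a rectangular 3D box of PET voxels (SUV units, mm spacing) around
a brain tumor, read from NIfTI. The malignancy proxy is the
tumor-to-normal uptake ratio TNR = SUVt/SUVn, with SUVt the mean of the
hottest 1.0 cm^3 of tumor and SUVn the mean of a 1.0 cm^3 normal-tissue
reference region. Radiomic features are computed on the whole box without
masks: first-order statistics on original values, co-occurrence and
run-length statistics on 128-level discretized images, and per-gray-level
fractal dimensions. Features significantly Pearson-correlated with TNR
(p < 0.05, uncorrected) enter an L1-regularized linear model of
log10(TNR), refit on 300 random 70/30 train/test splits; predictions are
potentiated (10^x) before computing MAE/RMSE/Spearman on the TNR scale, and
predictors are ranked by how often the splits select them.

## Image model and NIfTI handling

Only spacing and origin are modeled. Header rotations/flips are *not*
normalized at load: every feature this pipeline emits is either
direction-averaged (GLCM/GLRLM over the 13 unique lattice directions) or
orientation-free (first-order, fractal, volume/surface), so axis
permutations cannot change results; and all fixtures the package writes are
canonical. Non-finite voxels are rejected with a count rather than imputed
— degradation is explicit, never silent. The writer emits NIfTI-1 with a
diagonal sform; float64 storage is the default so round-trips are lossless
(float32 is available and round-trips to ~1e-7 relative). The reader was
validated against nibabel in both directions (our writer → nibabel reader
and vice versa, NIfTI-1 and NIfTI-2).

## Discretization

Two schemes, both over all voxels of the box:

* **es** (equal size): L bins of width (max−min)/L; the last bin closed.
* **ep** (equal probability): the level of a value is
  `floor((pos_first − 1) · L / N) + 1` with `pos_first` the first position
  of that value in the sorted sample. A repeated value therefore never
  straddles a level edge, and with N distinct values level populations
  differ by at most 1.

Constant images are legal (level 1 only): flat background boxes must
degrade gracefully, not error. L defaults to 128 — the convention encoded
in the feature names (`_128`, `b128`) — and is configurable because most
properties are scale-invariant and testable at small L.

## Texture statistics

GLCMs are built for the 13 unique distance-1 offsets, symmetrized
(matrix + transpose), normalized, averaged entrywise, then summarized.
The statistic set (contrast, homogeneity, homogeneity², cluster
prominence/shade/difference, two inverse-Gaussian kernels — one measuring
distance from the diagonal, one from the matrix's maximal cell) follows a
frozen formula table in `?glcm_statistics`; the upstream naming convention
preserves tokens like `Cluster_p_s_nd` and `Inv_Gauss_2p_s` whose exact
reference formulas are not public, so the formulas here are the package's
own, documented and oracle-tested. Each statistic also has a
"non-diagonal" (`_nd`) variant: diagonal cells removed, matrix
renormalized, missing when all mass is diagonal. Whether the reference
implementation renormalizes after removing the diagonal is unknown; this
choice is frozen and documented rather than guessed both ways.

GLRLMs count maximal same-level runs along every lattice line per
direction; GLN/RLN/SRE/LRE are averaged over the 13 directions. A
conservation invariant (each voxel in exactly one maximal run:
Σ r·count(g,r) = voxel count) is property-tested, and both matrix builders
are tested against exhaustive enumeration oracles to 1e-10.

## Geometric features and fractal dimensions

Per gray level g the **superlevel set** (level ≥ g) is used, not the
equality set: superlevel sets are nested, robust at L = 128 where single
levels are sparsely occupied, and give monotone dimension profiles.
(Whether the upstream library used equality or superlevel sets is not
public; this is the package's choice.)

**Box counting**: boxes of side 1, 2, 4, ... up to half the largest edge,
anchored at the volume corner (no offset averaging — determinism over
sophistication); the dimension is the OLS slope of log N(s) vs log(1/s)
over all sizes, needing ≥ 3 sizes, clamped to [0, 3]. Empty masks yield
missing values, not errors.

**Correlation dimension** (Grassberger–Procaccia): over occupied-voxel
centers in mm, C(r) = fraction of pairs within r, slope of log C vs log r.
Three numerical choices matter on a lattice, all fixed by validation
against analytic sets of known dimension (line 1, plane 2, solid 3 — the
test suite's tolerances are ±0.2/±0.25/±0.3):

1. radii are *empirical distance quantiles* at log-spaced probability
   targets (12 by default), so they track the discrete distance set instead
   of falling between steps;
2. each C step, constant on [d_i, d_{i+1}), is represented at the geometric
   midpoint of the interval, and the smallest realized distance (strongest
   lattice-shell distortion) is dropped;
3. the fit uses the scaling window C(r) ≤ 0.1 — below the saturation
   shoulder where the set's finite extent flattens the curve — relaxed to
   0.5 then 1 if fewer than 3 radii qualify. A fixed-decile radius window
   was tried first and rejected: it systematically underestimates solid
   sets (≈2.4 for a filled 16³ cube) because it drags saturated radii into
   the fit.

Pair counting is O(M²), so masks larger than 2000 voxels are subsampled
uniformly under a fixed internal seed; the estimate is deterministic and
the caller's RNG stream is untouched. Volume is voxel count × voxel
volume; surface counts exposed faces (including volume-boundary faces)
weighted by physical face area — a face-count surface, not marching cubes.

## TNR quantification

The hottest-region search slides a cube whose edge is
round((1000 mm³ / voxel volume)^(1/3)) voxels — 5 voxels at the default
2 mm spacing, giving exactly 1.000 cm³ — using a 3D summed-area table, so
the search is exhaustive and exact (verified against brute force). A cube
rather than a sphere keeps exactness cheap; the clinical VOI shape is not
public. The reference region is a planted box in synthetic data; anatomical
localization (contralateral frontal lobe) is expert knowledge outside this
package's scope. TNR is invariant under global intensity scaling, which is
property-tested.

## The stability protocol

* **Filter**: Pearson r per feature vs TNR, two-sided p from the t
  transform with n−2 df, keep p < 0.05, *no multiple-testing correction* —
  deliberately mirroring the two-step protocol this pipeline reimplements.
  By default the filter runs once on the **full dataset** before the split
  loop, as that protocol describes. This is an acknowledged optimistic-bias
  source: in a shuffled-label experiment the chance-correlated features
  that survive a full-data filter inflate apparent test-split correlations
  to a median |rho| near 0.4. The leakage-free alternative
  (`filter_per_split = TRUE`) recomputes the filter inside each training
  split; under it the shuffled-label null behaves correctly (median
  |rho| ≈ 0.08 in the acceptance test). Both modes are first-class; the
  default follows the reimplemented protocol, the flag exists for honest
  evaluation.
* **Split**: train size = round(0.7·n) (28 of 40), uniform without
  replacement, a pure function of the per-test seed.
* **Standardization**: training-split mean and sample (n−1) SD, reused on
  the test split. The upstream protocol is ambiguous about whether scaling
  used the full data; training-only is standard practice and is the
  default here.
* **LASSO**: glmnet on standardized predictors vs log10(TNR); penalty by
  5-fold CV on the training split (CV-minimum by default, "1se"
  available); the penalty rule is not specified upstream. An empty
  post-filter feature set yields a legal intercept-only model (protocols
  can select zero predictors).
* **Metrics**: always computed after potentiation, on the TNR scale.
  Spearman rho is missing (not 0) for constant predictions.
* **Aggregation**: medians and [25%; 75%] quartiles; per-feature
  occurrence count, share (% of tests) and mean |coefficient| among models
  that selected it, sorted by occurrence with ties broken by mean
  |coefficient| (at high signal many features saturate occurrence; the
  secondary key keeps the ranking informative).

One protocol property claimed in the build contract does **not** hold
empirically and is not asserted: shuffled labels do not drive the
*selected-predictor count* toward 0. The filter passes ≈ α·p
chance-correlated features in any case, and CV-chosen penalties keep many
of them in-model; what collapses under the null is generalization (rho),
not sparsity. The test suite asserts the rho null; the vignette records
the rest.

## Synthetic data: what it emulates and what it does not

A phantom is clipped-Gaussian background (mean 1, SD 0.1 SUV), an
ellipsoidal tumor whose voxels are base·(1 + amplitude·field) with `field`
unit-variance Gaussian-smoothed white noise of stated correlation length
(FFT convolution, circular), a planted k³ hotspot block set exactly to the
ground-truth SUVt (capped tumor texture keeps it the global argmax, so the
sliding-window search recovers SUVt *exactly*), and a planted reference box
whose realized mean is recentered to the ground-truth SUVn. Cohorts draw
per-case texture amplitude a ~ U(0.1, 0.5) and plant
log10(TNR) = log10(3.3) + 0.8·(a − 0.3) + ε, ε ~ N(0, 0.03), with a common
reference mean of 2.0 SUV — numbers chosen once so the realized TNR spans
≈1.9–5.6 with median near 3.3, the clinically observed envelope for this
tracer, without claiming to reproduce any patient distribution. Default
geometry is a 64³ box at 2 mm isotropic spacing (the true exported voxel
size is not public; 2 mm is a typical brain-PET reconstruction).

What phantoms do *not* model: PET physics (no partial-volume, scanner blur
or Poisson sinogram noise), anatomy (no frontal-lobe rule — the reference
box is ground truth), and MRI co-registration (upstream of this package).
A green end-to-end test therefore establishes that the *software* recovers
planted statistical structure, not that the biological claim holds.

For protocol-level validation at scale, `simulate_feature_cohort()`
bypasses images entirely: i.i.d. N(0,1) features of which the first 10
carry β = 0.06 each on log10(TNR) with residual SD 0.08 (≈85% of
log-target variance in the signal). On 200 cases × 500 features the
acceptance suite requires the 10 planted drivers to occupy the top 10
occurrence ranks and median test rho ≥ 0.7.

## Determinism

Every stochastic step (cohort draws, phantom noise, splits, CV folds,
correlation-dimension subsampling) derives its seed from a master seed and
restores the caller's RNG state. Two runs of simulate → extract → fit with
the same master seed produce byte-identical NIfTI files and aggregate
reports; the acceptance suite checks this at reduced per-case scale
(24³ voxels, L = 8, subsampled pair counts), which is sufficient because
determinism is scale-invariant.

## Known limitations

* The GLCM statistic formulas behind the preserved upstream names are this
  package's own frozen definitions; numerical values are not comparable to
  the (unpublished) reference implementation, only the naming contract is.
* The correlation-dimension estimator is tuned for voxel superlevel sets;
  very sparse masks (< ~10 voxels) return missing or noisy estimates by
  design.
* The full-data Pearson filter is optimistically biased (see above); use
  `filter_per_split = TRUE` when unbiased generalization estimates matter.
* Config files are JSON, not YAML (no YAML parser in the supported
  dependency set).
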