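---
title: "Eigenbrain synthesis of functional neuroimages: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenbrain synthesis of functional neuroimages: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eigensynth)
```

## The generative model

`eigensynth` treats a set of `K` spatially co-registered functional brain
volumes (PET or SPECT), reduced under a mask to a `K x N` matrix `X` of
voxel intensities, as draws from a small number of class-conditional
distributions. The model has three layers.

**Intensity scale.** Raw nuclear-imaging intensities carry arbitrary
per-subject scale (uptake, exposure, scanner gain). `normalize_to_max()`
divides each subject by the mean of its top-fraction in-mask intensities
(default fraction 0.03, minimum one voxel, `ceiling(fraction * N)` values
taken by count from the sorted array so boundary ties are deterministic).
The normalizer is computed within the mask only — outside voxels are
background by construction. The operation is scale-equivariant,
rank-preserving and idempotent; per-subject normalizers are recorded in
the returned dataset.

**Common linear basis.** The dataset-global voxelwise mean is subtracted
and `X` is factored by economy-size SVD; the right singular vectors are
the eigenbrains, a single orthonormal basis shared by all classes. A
shared basis — rather than per-class PCA — is essential: it makes latent
coordinates of different classes directly comparable and lets one
synthetic sampler serve any class. Centering is dataset-global for the
same reason; the mean is re-added at reconstruction (the inverse
transform is the transpose because the basis is orthonormal). After
centering the rank is at most `K - 1`; the default truncation `L` is the
full numerical rank (singular values above `1e-8` of the largest), i.e.
"all components", and rank deficiency is handled by capping rather than
erroring. Each eigenbrain's sign is fixed so that its largest-magnitude
voxel loading is positive, which makes bases reproducible across SVD
implementations. Voxel linearization is R's native column-major
(first-axis-fastest) order over the mask's true voxels, fixed and
documented so serialized bundles stay portable.

**Latent class densities.** Two interchangeable estimators model the
scores of each class:

* `fit_mvn()`: a joint multivariate normal with the class sample mean and
  a shrunk covariance `(1 - alpha) * S + alpha * (tr(S)/L) * I`. The
  intensity `alpha` is the Ledoit–Wolf minimum-MSE estimate for the
  scaled-identity target (the standard well-conditioned choice), computed
  from the `1/K_c` empirical covariance. Shrinkage guarantees positive
  definiteness even with fewer subjects than dimensions — the typical
  regime at full `L`. The density normalizer uses the latent dimension
  `L` in the `(2*pi)^(d/2)` term. The joint model preserves
  cross-component dependence, which is exactly why it can overfit: as `L`
  grows the fitted clusters concentrate and synthetic subjects drift
  toward the class centroid.
* `fit_kde_component()`: one univariate Gaussian-kernel KDE per retained
  component and class. Components are modeled independently — PCA scores
  are uncorrelated by construction and the residual dependence is small —
  which sacrifices conditional structure but resists overfitting and
  captures the heavy-tailed, asymmetric score distributions seen in
  pathological populations. Bandwidths come from the diffusion (improved
  Sheather–Jones) fixed point: the binned data (2^14 grid spanning the
  range padded 10% per side) is cosine-transformed and the smoothing-time
  fixed point solved to 1e-9, with the bracketing interval grown from
  0.1 upward if needed; when no root exists (tiny or pathological
  samples) the estimator falls back to Silverman's rule
  `1.06 * sd * n^(-1/5)` with a warning. On multimodal data the diffusion
  bandwidth deliberately undersmooths relative to Silverman; on Gaussian
  data the two agree asymptotically.

**Sampling.** KDE classes are sampled by inverse-transform: each
component's PDF is integrated by cumulative trapezoids on a 4096-point
grid spanning the observed scores plus six bandwidths per side,
renormalized to end exactly at 1, and inverted by linear interpolation
(flat CDF stretches are collapsed first so the inverse is well defined;
uniform draws at 0/1 clamp to the grid ends). Each component consumes an
independent uniform stream, consistent with the independence assumption
of the per-component model. MVN classes are sampled by a direct
`mu + R'z` Cholesky draw — per-coordinate CDF inversion would destroy
precisely the cross-component correlations the joint model exists to
keep. Reconstructed rows may go slightly negative through a truncated
basis; clipping at zero is available but off by default, because it
breaks the exactness of the linear reconstruction.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fraction` (normalization) | 0.03 | fraction of in-mask voxels | classic top-3% rule for FDG-PET/DaTSCAN |
| `L` (truncation) | full rank | components | "all components" convention; sweep + 1-SD rule for an optimum |
| `estimator` | `"kde"` | — | works untuned; `"mvn"` preferred once `L` is chosen |
| `grid_points` (CDF) | 4096 | points | interpolation error far below sampling noise |
| KDE grid size | 2^14 | bins | diffusion-bandwidth convention |
| `c_grid` (SVM) | 0.01–100, decade steps | — | standard span for a linear SVM cost search |
| `folds` / `inner_folds` | 10 / 5 | — | the standard nested-CV layout for VAF |
| `alpha` (FWE) | 0.05 | — | conventional family-wise level |
| `n_perm` | 1000 | permutations | maxT resolution ~1/1000 at the 95th percentile |

## The validation battery

`vaf_cross_validate()` is the reference analysis: a linear SVM on raw
voxel intensities, stratified outer folds, cost chosen per fold by inner
cross-validation on the training portion only. The first-listed (disease)
class is the positive class for sensitivity/specificity. Internally the
training rows are rotated into an orthonormal basis of their own row
space before fitting; because a linear SVM's weight vector lies in the
span of its training rows, predictions are mathematically identical to
fitting on raw voxels (asserted in a unit test), while fits become
orders of magnitude faster at `N >> K`. Feature scaling is disabled —
voxels enter the classifier as-is.

`experiment_generalization()` refits the entire synthesis model inside
each fold on the training portion only and tests the synthetic-trained
classifier on held-out real subjects; the leakage contract (held-out data
touch nothing trained) is tested by corrupting a held-out subject and
checking the fold's chosen cost is unchanged. `select_optimal_L()`
implements the one-standard-deviation rule: the highest `L` whose
synthetic-trained accuracy stays within one baseline SD of the real-data
baseline — a synthetic model that *beats* the baseline is treated as
overfitting evidence, not as improvement. `experiment_resubstitution()`
measures dependence: train on all real data, compare resubstitution
accuracy with accuracy on synthetic sets drawn from that same data (five
independent sets give the spread). A near-zero gap at full `L` under the
MVN, a larger gap under the KDE, and a larger gap again for MVN at the
optimal `L` is the expected ordering, and is what the acceptance checks
assert.

`tmap_two_sample()` computes pooled-variance two-sample t statistics per
voxel (`df = K_a + K_b - 2`; voxels with zero pooled variance get `t = 0`
by convention) with two FWE corrections: two-sided Bonferroni, and
permutation maxT where the observed labeling is included in the null set,
making the test exact-conservative. Random-field-theory thresholds are
deliberately not implemented; Bonferroni is conservative and maxT is
exact under exchangeability, which phantom simulations can verify
directly.

## What the phantoms emulate — and what they do not

`generate_phantom()` builds each subject as an ellipsoidal template plus
class-specific spherical intensity effects plus a few smooth orthonormal
variation modes weighted by Gaussian subject loadings plus voxel noise,
then smooths (separable truncated Gaussian, `sigma = fwhm / 2.3548`) and
clips at zero. This reproduces the statistical structure the model
assumes: overlapping classes with regional mean differences, smooth
spatial correlation, low-rank subject variability, nonnegative
intensities. The ADNI-like preset has three classes with the intermediate
class's (MCI) effect amplitude set exactly halfway between controls and
the strong class; the PPMI-like preset has two small bilateral
high-uptake regions, dimmed and made asymmetric in the disease class.
Preset sizes are desk-scale — 40 subjects per class on a 20^3 grid — and
effect amplitude −0.10 (template peak 1, noise SD 0.5 before smoothing)
was chosen once so that the strong scenario classifies around the
mid-0.8s and the intermediate one in the 0.7s, the moderate-overlap
regime the presets are meant to emulate. Phantoms deliberately omit
scanner physics (point-spread anisotropy, attenuation, Poisson count
noise) and anatomical realism; passing tests demonstrate statistical
correctness of the pipeline, not clinical realism of any synthetic image.

## Numerical choices and degenerate inputs

* All densities are computed in log space through Cholesky factors;
  underflow would otherwise be immediate at `L` in the hundreds.
* Numerical rank uses a relative `1e-8` singular-value cutoff; a dataset
  of identical images (zero variance) raises a degenerate-data error, as
  do classes with fewer than two subjects or latent components with all
  scores identical (the error names class and component).
* The implicit mask (no mask supplied) keeps voxels strictly positive in
  at least one subject — appropriate for nuclear modalities whose
  background is zero — and its use is announced in a message. Affines
  must agree entrywise within relative 1e-4; registration itself is out
  of scope.
* Volumes are written as float32 NIfTI-1 (standard for these
  derivatives); all in-memory computation is float64.
* Model bundles serialize as a JSON metadata file plus plain CSV arrays —
  deliberately text-only and toolchain-neutral.
* Every stochastic entry point takes an explicit seed; per-class and
  per-fold sub-seeds are derived deterministically, so identical
  configuration and seed give bit-identical synthetic datasets.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on phantoms:
24^3/50 subjects for decomposition exactness, 14^3/50+50 for the
synthetic-vs-original null t-maps (20 seeds, 200 permutations), the
20^3/120-subject ADNI-like preset for the classification experiments
(200 synthetic subjects per class, the harness default), 20^3/400 for
latent-separation recovery, and 200 repetitions of a 10^3 global-null
phantom for the family-wise error check. These sizes were chosen as the
smallest at which each statistical property is comfortably resolved.

## Known limitations

* The KDE route ignores residual cross-component dependence; the MVN
  route assumes Gaussian scores. Heavy-tailed joint models (e.g.
  alpha-stable) and multivariate KDE are out of scope.
* `L` selection by the 1-SD rule requires a trustworthy baseline; with
  very small datasets the baseline SD is wide and the rule permissive.
* Bonferroni is conservative under the strong spatial correlation of
  smoothed images; maxT is preferred whenever permutations are
  affordable.
* Inputs must already be spatially normalized; no registration, no DICOM,
  no 4D time series.
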