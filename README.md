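# eigensynth

Generative synthesis of functional brain images (PET/SPECT) from an
existing co-registered dataset, for data augmentation, standardized
evaluation of computer-aided-diagnosis (CAD) pipelines, and teaching.

## The problem and the method

Nuclear-imaging datasets for neurodegenerative disease (FDG-PET in
Alzheimer's disease, DaTSCAN SPECT in Parkinson's disease) are small and
access-restricted, which makes CAD classifiers hard to compare and easy to
overfit. `eigensynth` builds a per-class generative model of such a dataset
and draws new, independent images from it:

1. **Intensity normalization.** Each subject's image *I* is rescaled to
   *I′ = I / Iₙ*, where *Iₙ* is the mean of its top 3% in-mask intensities,
   so voxel values are directly comparable across subjects.
2. **Eigenbrain decomposition.** The subjects-by-voxels matrix *X*
   (*K* × *N*) is centered and factored by SVD, *X = U D Vᵀ*. The columns
   of *W = V* are the *eigenbrains*: an orthonormal basis of inter-subject
   variance modes. Subject coordinates (scores) are *S_L = X W_L* for the
   first *L* components.
3. **Per-class latent density.** The class-*c* scores are modeled either by
   a multivariate normal *N(μᶜ, Σᶜ)* with Ledoit–Wolf shrinkage
   Σᶜ = (1−α)·Σ_emp + α·(tr Σ_emp / L)·I (joint model, preserves
   cross-component structure), or by independent per-component Gaussian
   kernel density estimates with diffusion (improved Sheather–Jones)
   bandwidths (robust to heavy tails, less prone to overfitting).
4. **Sampling and reconstruction.** New latent coordinates are drawn by
   inverse-CDF sampling of each tabulated KDE (or a joint Cholesky draw for
   the MVN) and mapped back to voxel space, *X̂ᶜ = Ŝᶜ W_Lᵀ + mean*.

A validation battery quantifies whether the synthetic images keep the class
structure without copying the originals: voxels-as-features (VAF) linear
SVM with nested cross-validation, a train-on-synthetic/test-on-real
generalization experiment, a resubstitution experiment measuring dependence
on the source data, a one-standard-deviation rule for choosing *L*, and
mass-univariate two-sample t-maps with Bonferroni or permutation-maxT
family-wise error (FWE) control. A 3D phantom generator with known ground
truth makes the whole pipeline testable without clinical data.

## Worked example

```r
library(eigensynth)

ph <- phantom_adni_like()          # NOR / MCI / AD phantom, known truth
ds <- ph$dataset
model <- fit_synthesis_model(ds, estimator = "mvn")
syn <- synthesize_dataset(model, n_per_class = 200, seed = 3)

glance(vaf_cross_validate(ds,  "AD", "NOR", seed = 2))[, 1:2]
#> # A tibble: 1 x 2
#>   accuracy accuracy_sd
#>      <dbl>       <dbl>
#> 1    0.838      0.0844
glance(vaf_cross_validate(syn, "AD", "NOR", seed = 2))[, 1:2]
#> # A tibble: 1 x 2
#>   accuracy accuracy_sd
#>      <dbl>       <dbl>
#> 1    0.945      0.0369
```

The real phantom data separate AD from NOR at 0.838 accuracy; a classifier
trained and evaluated on 200 synthetic subjects per class sees the same
class structure (0.945 — slightly concentrated, the known full-*L* MVN
behavior). The strong-vs-control scenario stays easier than the
intermediate one in both real and synthetic data, and a two-sample
permutation t-map between a population and its synthetic counterpart shows
no FWE-significant voxels:

```r
one <- generate_phantom(phantom_spec(n_per_class = c(A = 50), seed = 5001))
m1 <- fit_synthesis_model(one$dataset)        # per-component KDE default
s1 <- synthesize(m1, "A", 50, seed = 6001)
tmap_two_sample(one$dataset$data, s1$data, correction = "permutation",
                n_perm = 200, seed = 7001)
#> <tmap_result> permutation FWE at alpha = 0.05: threshold |t| > 4.451
#>   (df = 98), 0 / 3648 voxels significant
```

A command-line front end (`inst/cli/eigensynth.R`) wires the same steps for
shell use: `phantom`, `fit`, `synthesize`, `validate`, `tmap`; see
`?run_cli`.

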