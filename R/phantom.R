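#' Specification of a 3D brain-like phantom dataset
#'
#' Describes a synthetic population with known ground truth: a shared
#' ellipsoidal "brain" template, per-class spherical regional intensity
#' effects, a small number of smooth ground-truth variation modes with
#' per-mode subject loadings, voxelwise Gaussian noise, and global
#' Gaussian smoothing. Each field maps to a feature of real PET/SPECT
#' populations: overlapping classes, regional class effects, and smooth
#' spatially correlated subject variability.
#'
#' @param shape Grid size, default `c(24, 24, 24)` (keeps a full pipeline
#'   run well under a minute).
#' @param n_per_class Named integer vector of subjects per class (>= 2
#'   each).
#' @param class_effects Named list (one entry per class) of effect lists;
#'   each effect is `list(center = c(i, j, k), radius = r, amplitude = a)`
#'   adding `a` inside the sphere. Amplitudes are in template intensity
#'   units (template peak is 1); radii must be < min(shape)/2.
#' @param latent_dim Number of smooth ground-truth variation modes shared
#'   by all classes.
#' @param latent_sd Per-mode standard deviations of the subject loadings.
#' @param noise_sd Voxelwise Gaussian noise SD (before smoothing).
#' @param smoothing_fwhm Full width at half maximum, in voxels, of the
#'   final Gaussian smoothing (`sigma = fwhm / 2.3548`).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24, 24, 24),
                         n_per_class = c(A = 25, B = 25),
                         class_effects = NULL,
                         latent_dim = 4,
                         latent_sd = c(0.6, 0.4, 0.25, 0.15),
                         noise_sd = 0.5,
                         smoothing_fwhm = 2,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    abort("`shape` must be 3 integers >= 4.",
          class = "eigensynth_specification_error")
  }
  if (is.null(names(n_per_class)) || any(n_per_class < 2L)) {
    abort("`n_per_class` must be a named vector with >= 2 subjects per class.",
          class = "eigensynth_specification_error")
  }
  if (is.null(class_effects)) {
    class_effects <- stats::setNames(
      rep(list(list()), length(n_per_class)), names(n_per_class))
  }
  for (cl in names(class_effects)) {
    for (eff in class_effects[[cl]]) {
      if (!is.finite(eff$amplitude) || eff$radius >= min(shape) / 2) {
        abort("effect amplitudes must be finite and radii < min(shape)/2.",
              class = "eigensynth_specification_error")
      }
    }
  }
  if (length(latent_sd) != latent_dim || any(latent_sd < 0)) {
    abort("`latent_sd` must have one nonnegative entry per mode.",
          class = "eigensynth_specification_error")
  }
  structure(list(shape = shape, n_per_class = n_per_class,
                 class_effects = class_effects, latent_dim = latent_dim,
                 latent_sd = latent_sd, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable truncated-Gaussian smoothing; rows renormalized at edges
gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  Kmat <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  Kmat[abs(row(Kmat) - col(Kmat)) > ceiling(4 * sigma)] <- 0
  sweep(Kmat, 1L, rowSums(Kmat), `/`)
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with a truncated, edge-renormalized Gaussian along
#' each axis in turn; `sigma = fwhm / 2.3548`.
#'
#' @param arr Numeric 3D array.
#' @param fwhm Full width at half maximum in voxels (0 = no smoothing).
#' @return Smoothed array of the same shape.
#' @export
gauss_smooth_3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / 2.3548
  d <- dim(arr)
  for (ax in 1:3) {
    Kmat <- gaussian_kernel_matrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = d[ax])
    m <- Kmat %*% m
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

ellipsoid_template <- function(shape) {
  ctr <- (shape + 1) / 2
  radii <- 0.40 * shape
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  rho2 <- ((g$i - ctr[1]) / radii[1])^2 + ((g$j - ctr[2]) / radii[2])^2 +
    ((g$k - ctr[3]) / radii[3])^2
  vals <- ifelse(rho2 <= 1, 1 - 0.3 * rho2, 0)
  array(vals, dim = shape)
}

sphere_mask <- function(shape, center, radius) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  r2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  array(r2 <= radius^2, dim = shape)
}

#' Generate a phantom dataset with known ground truth
#'
#' Each subject's image is built as
#' `template + class effect spheres + sum_m z_m * mode_m + noise`,
#' then Gaussian-smoothed at `smoothing_fwhm` and clipped at zero. The
#' variation modes are smooth random fields, orthonormalized over the
#' in-mask (template > 0) voxels, shared by all classes; the subject
#' loadings `z_m ~ N(0, latent_sd_m^2)` are the ground-truth latent
#' coordinates. Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `dataset` (a [voxel_dataset()]) and `truth`
#'   (list: `class_means` — noise-free smoothed per-class mean rows,
#'   `latent` — K x latent_dim loading matrix, `modes` — in-mask mode
#'   matrix, `effect_masks` — per-class voxel masks of the effect
#'   spheres).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    shape <- spec$shape
    template <- ellipsoid_template(shape)
    mask <- template > 0
    n_mask <- sum(mask)
    classes <- names(spec$n_per_class)
    # smooth random modes, orthonormal over in-mask voxels
    modes <- NULL
    if (spec$latent_dim > 0) {
      raw <- sapply(seq_len(spec$latent_dim), function(m) {
        field <- gauss_smooth_3d(array(rnorm(prod(shape)), dim = shape), 4)
        field[mask]
      })
      qr_d <- qr(raw)
      modes <- qr.Q(qr_d)[, seq_len(spec$latent_dim), drop = FALSE]
    }
    class_vol <- lapply(classes, function(cl) {
      vol <- template
      for (eff in spec$class_effects[[cl]]) {
        vol <- vol + eff$amplitude * sphere_mask(shape, eff$center, eff$radius)
      }
      vol
    })
    names(class_vol) <- classes
    effect_masks <- lapply(classes, function(cl) {
      m <- array(FALSE, dim = shape)
      for (eff in spec$class_effects[[cl]]) {
        m <- m | sphere_mask(shape, eff$center, eff$radius)
      }
      m[mask]
    })
    names(effect_masks) <- classes
    K <- sum(spec$n_per_class)
    labels <- rep(classes, times = spec$n_per_class)
    latent <- matrix(0, K, max(spec$latent_dim, 1))
    data <- matrix(0, K, n_mask)
    class_means <- matrix(0, length(classes), n_mask,
                          dimnames = list(classes, NULL))
    for (ci in seq_along(classes)) {
      sm <- pmax(gauss_smooth_3d(class_vol[[classes[ci]]],
                                 spec$smoothing_fwhm), 0)
      class_means[ci, ] <- sm[mask]
    }
    for (k in seq_len(K)) {
      vol <- class_vol[[labels[k]]]
      if (spec$latent_dim > 0) {
        z <- rnorm(spec$latent_dim, sd = spec$latent_sd)
        latent[k, seq_len(spec$latent_dim)] <- z
        contrib <- array(0, dim = shape)
        contrib[mask] <- as.numeric(modes %*% z)
        vol <- vol + contrib
      }
      if (spec$noise_sd > 0) {
        vol <- vol + array(rnorm(prod(shape), sd = spec$noise_sd), dim = shape)
      }
      vol <- pmax(gauss_smooth_3d(vol, spec$smoothing_fwhm), 0)
      data[k, ] <- vol[mask]
    }
    geometry <- volume_geometry(shape)
    ds <- voxel_dataset(data, labels, mask, geometry,
                        subject_ids = sprintf("ph_%s_%03d", labels,
                                              sequence(spec$n_per_class)))
    list(dataset = ds,
         truth = list(class_means = class_means, latent = latent,
                      modes = modes, effect_masks = effect_masks,
                      template = template[mask]))
  })
}

#' ADNI-like three-class phantom (NOR / MCI / AD)
#'
#' Emulates an FDG-PET population with a progressive disorder: two
#' hypometabolic effect spheres whose amplitude in the intermediate class
#' (MCI) is set exactly halfway between controls (no effect) and the
#' strong class (AD), giving moderately overlapping classes. Defaults are
#' desk-scale (40 subjects per class on a 20^3 grid).
#'
#' @param n_per_class Named counts for NOR, MCI, AD.
#' @param shape Grid size.
#' @param effect_amplitude AD sphere amplitude (negative = hypometabolism);
#'   MCI receives half of it.
#' @param noise_sd,latent_sd,smoothing_fwhm As in [phantom_spec()].
#' @param seed Integer seed.
#' @return As [generate_phantom()]: list with `dataset` and `truth`.
#' @export
phantom_adni_like <- function(n_per_class = c(NOR = 40, MCI = 40, AD = 40),
                              shape = c(20, 20, 20),
                              effect_amplitude = -0.10,
                              noise_sd = 0.5,
                              latent_sd = c(0.6, 0.4, 0.25, 0.15),
                              smoothing_fwhm = 2,
                              seed = 17L) {
  ctr <- round((shape + 1) / 2)
  sph <- function(amp) list(
    list(center = ctr + c(-3, 3, 1), radius = 2.6, amplitude = amp),
    list(center = ctr + c(3, 3, 1), radius = 2.6, amplitude = amp),
    list(center = ctr + c(0, -4, -2), radius = 2.2, amplitude = amp))
  spec <- phantom_spec(
    shape = shape, n_per_class = n_per_class,
    class_effects = list(NOR = list(), MCI = sph(effect_amplitude / 2),
                         AD = sph(effect_amplitude)),
    latent_dim = length(latent_sd), latent_sd = latent_sd,
    noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm, seed = seed)
  generate_phantom(spec)
}

#' PPMI-like two-class phantom (NOR / PD)
#'
#' Emulates a DaTSCAN population: two small bilateral high-uptake
#' ("striatum-like") regions whose amplitude is strongly reduced, and
#' made asymmetric, in the disease class — a well separated two-class
#' problem.
#'
#' @param n_per_class Named counts for NOR and PD.
#' @param shape Grid size.
#' @param nor_amplitude Uptake amplitude of both regions in controls.
#' @param pd_amplitude Mean uptake amplitude in the disease class;
#'   `asymmetry` is added to one side and subtracted from the other.
#' @param asymmetry Left/right amplitude difference in the disease class.
#' @param noise_sd,latent_sd,smoothing_fwhm As in [phantom_spec()].
#' @param seed Integer seed.
#' @return As [generate_phantom()]: list with `dataset` and `truth`.
#' @export
phantom_ppmi_like <- function(n_per_class = c(NOR = 40, PD = 40),
                              shape = c(20, 20, 20),
                              nor_amplitude = 1.2,
                              pd_amplitude = 0.55,
                              asymmetry = 0.1,
                              noise_sd = 0.5,
                              latent_sd = c(0.6, 0.4, 0.25, 0.15),
                              smoothing_fwhm = 2,
                              seed = 19L) {
  ctr <- round((shape + 1) / 2)
  left <- ctr + c(-4, 1, 0)
  right <- ctr + c(4, 1, 0)
  spec <- phantom_spec(
    shape = shape, n_per_class = n_per_class,
    class_effects = list(
      NOR = list(list(center = left, radius = 2.2, amplitude = nor_amplitude),
                 list(center = right, radius = 2.2, amplitude = nor_amplitude)),
      PD = list(list(center = left, radius = 2.2,
                     amplitude = pd_amplitude - asymmetry),
                list(center = right, radius = 2.2,
                     amplitude = pd_amplitude + asymmetry))),
    latent_dim = length(latent_sd), latent_sd = latent_sd,
    noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm, seed = seed)
  generate_phantom(spec)
}
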