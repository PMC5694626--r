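#' Tabulate the CDF of a per-component KDE
#'
#' Computes `F(x)` on a regular grid spanning the observed scores padded by
#' six bandwidths on each side, by cumulative trapezoidal integration of
#' [kde_pdf()], renormalized so the final value is exactly 1. The table is
#' the numerical device behind inverse-transform sampling.
#'
#' @param model A `kde_component_model`.
#' @param grid_points Grid resolution (default 4096).
#' @return Object of class `tabulated_cdf`: list with strictly increasing
#'   `grid` and nondecreasing `cdf` in `[0, 1]`.
#' @export
tabulate_cdf <- function(model, grid_points = 4096) {
  stopifnot(inherits(model, "kde_component_model"))
  h <- model$bandwidth
  grid <- seq(min(model$points) - 6 * h, max(model$points) + 6 * h,
              length.out = grid_points)
  f <- kde_pdf(model, grid)
  dx <- diff(grid)
  increments <- dx * (head(f, -1) + tail(f, -1)) / 2
  cdf <- c(0, cumsum(increments))
  cdf <- cdf / cdf[length(cdf)]
  structure(list(grid = grid, cdf = cdf), class = "tabulated_cdf")
}

#' Inverse-CDF sampling from a tabulated CDF
#'
#' Draws `u ~ Uniform(0, 1)` and linearly interpolates the grid against the
#' tabulated CDF at query `u`. Flat CDF regions (zero-density gaps) are
#' handled by collapsing duplicate CDF values before interpolation, so the
#' inverse is well defined; `u` at 0/1 maps to the first/last grid value.
#'
#' @param cdf A `tabulated_cdf`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Deterministic given the RNG state;
#'   seed upstream with `set.seed()` or `withr::with_seed()`.
#' @export
sample_inverse_cdf <- function(cdf, n) {
  stopifnot(inherits(cdf, "tabulated_cdf"))
  u <- runif(n)
  invert_cdf(cdf, u)
}

invert_cdf <- function(cdf, u) {
  keep <- c(TRUE, diff(cdf$cdf) > 0)
  approx(cdf$cdf[keep], cdf$grid[keep], xout = u, rule = 2)$y
}

#' Direct sampling from a fitted multivariate normal class model
#'
#' Draws `mu + R'z` with `z` standard normal and `R` the upper Cholesky
#' factor of the shrunk covariance. A direct multivariate draw (rather than
#' per-coordinate CDF inversion) preserves the cross-component correlations
#' the joint model exists to capture.
#'
#' @param model An `mvn_class_model`.
#' @param n Number of draws.
#' @return `n x L` matrix of latent coordinates.
#' @export
sample_mvn <- function(model, n) {
  stopifnot(inherits(model, "mvn_class_model"))
  L <- length(model$mu)
  Z <- matrix(rnorm(n * L), n, L)
  sweep(Z %*% model$chol, 2L, model$mu, `+`)
}

#' Fit the full synthesis model: eigenbrains plus per-class densities
#'
#' Convenience wrapper running [fit_eigenbrains()], projecting the training
#' data at `L`, and fitting one latent density per class with the chosen
#' estimator.
#'
#' @param dataset A [voxel_dataset()] (already intensity-normalized if
#'   normalization is wanted; see [normalize_to_max()]).
#' @param estimator `"kde"` (per-component diffusion-bandwidth KDE) or
#'   `"mvn"` (joint shrinkage Gaussian).
#' @param L Truncation level; default the full rank.
#' @return Object of class `synthesis_model`: list with `eigenbrains`,
#'   `densities` (named per class), `estimator`, `L`, `classes`.
#' @export
fit_synthesis_model <- function(dataset, estimator = c("kde", "mvn"),
                                L = NULL) {
  estimator <- match.arg(estimator)
  eb <- fit_eigenbrains(dataset, L = L)
  scores <- project(dataset, eb, L = eb$L)
  classes <- levels(scores$labels)
  densities <- lapply(classes, function(cl)
    fit_class_density(scores, cl, estimator = estimator))
  names(densities) <- classes
  structure(list(eigenbrains = eb, densities = densities,
                 estimator = estimator, L = eb$L, classes = classes,
                 scores = scores),
            class = "synthesis_model")
}

#' @export
print.synthesis_model <- function(x, ...) {
  cat(sprintf("<synthesis_model> estimator %s, L = %d, classes: %s\n",
              x$estimator, x$L, paste(x$classes, collapse = ", ")))
  invisible(x)
}

draw_latent <- function(density, n) {
  if (density$estimator == "mvn") {
    sample_mvn(density$mvn, n)
  } else {
    # independent uniform stream per component, matching the
    # per-component independence assumption of the KDE model
    do.call(cbind, lapply(density$components, function(cm)
      sample_inverse_cdf(tabulate_cdf(cm), n)))
  }
}

#' Synthesize new images of one class
#'
#' Draws `n_samples` new latent coordinates from the fitted class density
#' (per-component inverse-CDF sampling for KDE; a joint Cholesky draw for
#' MVN) and reconstructs them through the eigenbrain basis with the dataset
#' mean re-added. Identical `seed` and parameters give bit-identical
#' output.
#'
#' @param model A [fit_synthesis_model()] object.
#' @param class_id Class to synthesize (must be among `model$classes`).
#' @param n_samples Number of synthetic subjects (default 200, the standard
#'   per-class count of the validation harness).
#' @param seed Integer seed for the draws.
#' @param clip_negative Clip negative voxels to zero? Default `FALSE`
#'   (keeps the linear reconstruction exact).
#' @return A [voxel_dataset()] of synthetic subjects labelled `class_id`,
#'   with provenance (`seed`, `estimator`, `L`) in attribute
#'   `"provenance"`.
#' @export
synthesize <- function(model, class_id, n_samples = 200, seed = 1L,
                       clip_negative = FALSE) {
  stopifnot(inherits(model, "synthesis_model"))
  if (!class_id %in% model$classes) {
    abort(sprintf("no fitted density for class '%s'.", class_id),
          class = "eigensynth_model_state_error")
  }
  if (n_samples < 1L) {
    abort("`n_samples` must be >= 1.", class = "eigensynth_value_error")
  }
  latent <- withr::with_seed(seed,
                             draw_latent(model$densities[[class_id]],
                                         n_samples))
  rows <- reconstruct(latent, model$eigenbrains)
  if (clip_negative) rows <- clip_nonnegative(rows)
  ds <- voxel_dataset(rows, rep(class_id, n_samples),
                      model$eigenbrains$mask, model$eigenbrains$geometry,
                      subject_ids = sprintf("syn_%s_%04d", class_id,
                                            seq_len(n_samples)))
  attr(ds, "provenance") <- list(seed = seed, estimator = model$estimator,
                                 L = model$L, class_id = class_id)
  ds
}

#' Synthesize a multi-class dataset
#'
#' Runs [synthesize()] for each class (each with its own derived seed) and
#' row-binds the results into one labelled dataset.
#'
#' @param model A `synthesis_model`.
#' @param n_per_class Either a single count applied to every class or a
#'   named vector over `model$classes`.
#' @param seed Master seed; per-class seeds are derived deterministically.
#' @param clip_negative Passed to [synthesize()].
#' @return A [voxel_dataset()].
#' @export
synthesize_dataset <- function(model, n_per_class = 200, seed = 1L,
                               clip_negative = FALSE) {
  classes <- model$classes
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)), classes)
  }
  parts <- lapply(seq_along(classes), function(i)
    synthesize(model, classes[i], n_per_class[[classes[i]]],
               seed = (seed + 7919L * i) %% .Machine$integer.max,
               clip_negative = clip_negative))
  data <- do.call(rbind, lapply(parts, function(p) p$data))
  labels <- unlist(lapply(parts, function(p) as.character(p$labels)))
  ids <- unlist(lapply(parts, function(p) p$subject_ids))
  voxel_dataset(data, labels, model$eigenbrains$mask,
                model$eigenbrains$geometry, subject_ids = ids)
}

# --- model bundle serialization --------------------------------------------

write_array_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
}

read_array_csv <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}

#' Save a synthesis model as a portable directory bundle
#'
#' Writes a JSON metadata file (geometry, estimator, L, classes, package
#' version) plus plain CSV arrays (mean, basis, singular values, per-class
#' density parameters). The bundle is the package's only model interchange
#' format and is readable by [load_model()].
#'
#' @param model A `synthesis_model`.
#' @param dir Bundle directory (created).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eb <- model$eigenbrains
  meta <- list(
    format = "eigensynth-bundle-1",
    package_version = as.character(utils::packageVersion("eigensynth")),
    estimator = model$estimator, L = model$L, classes = model$classes,
    K = eb$K, M = eb$M,
    shape = eb$geometry$shape, affine = eb$geometry$affine,
    voxel_units = eb$geometry$voxel_units
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(matrix(eb$mean, ncol = 1), file.path(dir, "mean.csv"))
  write_array_csv(eb$basis, file.path(dir, "basis.csv"))
  write_array_csv(matrix(eb$singular_values, ncol = 1),
                  file.path(dir, "singular_values.csv"))
  write_array_csv(matrix(as.integer(eb$mask), ncol = 1),
                  file.path(dir, "mask.csv"))
  write_array_csv(model$scores$scores, file.path(dir, "scores.csv"))
  write.csv(data.frame(label = as.character(model$scores$labels)),
            file.path(dir, "score_labels.csv"), row.names = FALSE)
  for (cl in model$classes) {
    d <- model$densities[[cl]]
    if (d$estimator == "mvn") {
      write_array_csv(matrix(d$mvn$mu, ncol = 1),
                      file.path(dir, sprintf("mvn_mu_%s.csv", cl)))
      write_array_csv(d$mvn$sigma,
                      file.path(dir, sprintf("mvn_sigma_%s.csv", cl)))
      jsonlite::write_json(list(alpha = d$mvn$alpha, K_c = d$mvn$K_c),
                           file.path(dir, sprintf("mvn_meta_%s.json", cl)),
                           auto_unbox = TRUE, digits = NA)
    } else {
      bw <- vapply(d$components, function(cm) cm$bandwidth, numeric(1))
      write_array_csv(matrix(bw, ncol = 1),
                      file.path(dir, sprintf("kde_bandwidths_%s.csv", cl)))
    }
  }
  invisible(dir)
}

#' Load a synthesis model bundle written by [save_model()]
#'
#' @param dir Bundle directory.
#' @return A `synthesis_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "eigensynth-bundle-1")) {
    abort("not an eigensynth model bundle.", class = "eigensynth_io_error")
  }
  geometry <- volume_geometry(meta$shape, matrix(meta$affine, 4, 4),
                              meta$voxel_units)
  mask <- array(as.logical(read_array_csv(file.path(dir, "mask.csv"))),
                dim = geometry$shape)
  eb <- structure(list(
    mean = as.numeric(read_array_csv(file.path(dir, "mean.csv"))),
    basis = unname(read_array_csv(file.path(dir, "basis.csv"))),
    singular_values = as.numeric(
      read_array_csv(file.path(dir, "singular_values.csv"))),
    L = as.integer(meta$L), M = as.integer(meta$M), K = as.integer(meta$K),
    mask = mask, geometry = geometry), class = "eigenbrain_model")
  scores <- eb_scores(
    unname(read_array_csv(file.path(dir, "scores.csv"))),
    read.csv(file.path(dir, "score_labels.csv"))$label)
  densities <- lapply(meta$classes, function(cl) {
    if (meta$estimator == "mvn") {
      mm <- jsonlite::read_json(file.path(dir, sprintf("mvn_meta_%s.json", cl)),
                                simplifyVector = TRUE)
      sigma <- unname(read_array_csv(file.path(dir,
                                               sprintf("mvn_sigma_%s.csv", cl))))
      mvn <- structure(list(
        class_id = cl,
        mu = as.numeric(read_array_csv(file.path(dir,
                                                 sprintf("mvn_mu_%s.csv", cl)))),
        sigma = sigma, alpha = mm$alpha, K_c = as.integer(mm$K_c),
        chol = chol(sigma)), class = "mvn_class_model")
      structure(list(estimator = "mvn", class_id = cl, L = meta$L, mvn = mvn),
                class = "class_density")
    } else {
      bw <- as.numeric(read_array_csv(file.path(dir,
                                                sprintf("kde_bandwidths_%s.csv", cl))))
      comps <- lapply(seq_len(meta$L), function(l)
        fit_kde_component(scores, cl, l, bandwidth = bw[l]))
      structure(list(estimator = "kde", class_id = cl, L = meta$L,
                     components = comps), class = "class_density")
    }
  })
  names(densities) <- meta$classes
  structure(list(eigenbrains = eb, densities = densities,
                 estimator = meta$estimator, L = as.integer(meta$L),
                 classes = meta$classes, scores = scores),
            class = "synthesis_model")
}
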