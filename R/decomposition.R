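#' Fit the eigenbrain basis by PCA via SVD
#'
#' Subtracts the dataset-global voxelwise mean image and computes the
#' economy-size singular value decomposition of the centered
#' subjects-by-voxels matrix `X = U D V'`. The columns of `V` are the
#' eigenbrains: an orthonormal basis of inter-subject variance modes,
#' ordered by nonincreasing singular value. The full `N x N` covariance is
#' never materialized (`K << N` in practice).
#'
#' The number of retained positive singular values `M` (the numerical rank,
#' at most `K - 1` after centering) bounds the truncation level `L`. By
#' default `L = M`, i.e. all available components, matching the convention
#' of using the first `L = K` components capped at rank. Each eigenbrain's
#' sign is fixed so its largest-magnitude voxel loading is positive, making
#' the basis reproducible across SVD implementations.
#'
#' @param dataset A [voxel_dataset()] with at least 2 subjects.
#' @param L Optional truncation level; defaults to the rank `M`.
#' @param rank_tol Relative tolerance on singular values used to decide the
#'   numerical rank (default `1e-8` times the largest singular value).
#' @return An object of class `eigenbrain_model` with fields `mean`
#'   (length-N), `basis` (N x M, orthonormal columns), `singular_values`
#'   (length M, nonincreasing), `L`, `K`, `mask`, `geometry`.
#' @export
fit_eigenbrains <- function(dataset, L = NULL, rank_tol = 1e-8) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  K <- nrow(dataset$data)
  if (K < 2L) {
    abort("at least 2 subjects are required to fit eigenbrains.",
          class = "eigensynth_insufficient_data_error")
  }
  mu <- colMeans(dataset$data)
  Xc <- sweep(dataset$data, 2L, mu)
  sv <- svd(Xc)
  d <- sv$d
  if (max(d) <= 0) {
    abort("all images are identical: no variance to decompose.",
          class = "eigensynth_degenerate_error")
  }
  M <- sum(d > max(d) * rank_tol)
  basis <- sv$v[, seq_len(M), drop = FALSE]
  u <- sv$u[, seq_len(M), drop = FALSE]
  # fix sign: largest-magnitude loading positive
  for (j in seq_len(M)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) {
      basis[, j] <- -basis[, j]
      u[, j] <- -u[, j]
    }
  }
  if (is.null(L)) L <- M
  L <- as.integer(L)
  if (L < 1L || L > M) {
    abort(sprintf("L = %d outside 1..M = %d.", L, M),
          class = "eigensynth_truncation_error")
  }
  structure(list(mean = mu, basis = basis,
                 singular_values = d[seq_len(M)],
                 L = L, M = M, K = K,
                 mask = dataset$mask, geometry = dataset$geometry),
            class = "eigenbrain_model")
}

#' @export
print.eigenbrain_model <- function(x, ...) {
  cat(sprintf(
    "<eigenbrain_model> %d components (rank) over %d voxels; K = %d, L = %d\n",
    x$M, length(x$mean), x$K, x$L))
  invisible(x)
}

#' Tidy an eigenbrain model into a per-component tibble
#'
#' @param x An `eigenbrain_model`.
#' @param ... Unused.
#' @return Tibble with `component`, `singular_value`, `variance_explained`
#'   (fraction of total centered variance).
#' @method tidy eigenbrain_model
#' @export
tidy.eigenbrain_model <- function(x, ...) {
  ev <- x$singular_values^2
  tibble::tibble(component = seq_along(ev),
                 singular_value = x$singular_values,
                 variance_explained = ev / sum(ev))
}

#' @method glance eigenbrain_model
#' @export
glance.eigenbrain_model <- function(x, ...) {
  tibble::tibble(K = x$K, n_voxels = length(x$mean), rank = x$M, L = x$L)
}

as_rows <- function(x, model) {
  if (inherits(x, "voxel_dataset")) {
    rows <- x$data
    labels <- x$labels
  } else {
    rows <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
    labels <- attr(x, "labels") %||% factor(rep(NA_character_, nrow(rows)))
  }
  if (ncol(rows) != length(model$mean)) {
    abort(sprintf("rows have %d voxels; model expects %d.",
                  ncol(rows), length(model$mean)),
          class = "eigensynth_dimension_error")
  }
  list(rows = rows, labels = labels)
}

#' Project images into eigenbrain score space
#'
#' Computes the latent scores `S_L = (X - mean) W_L`, the coordinates of
#' each image on the first `L` eigenbrains. For the training set these
#' equal `U D` truncated to `L` columns.
#'
#' @param x A [voxel_dataset()] or a numeric matrix/vector of voxel rows.
#' @param model An [fit_eigenbrains()] model.
#' @param L Truncation level, default `model$L`.
#' @return An object of class `eb_scores`: list with `scores` (K' x L
#'   matrix) and `labels` (factor, `NA` when projecting unlabelled rows).
#' @export
project <- function(x, model, L = model$L) {
  stopifnot(inherits(model, "eigenbrain_model"))
  L <- as.integer(L)
  if (L < 1L || L > model$M) {
    abort(sprintf("L = %d exceeds model rank M = %d.", L, model$M),
          class = "eigensynth_truncation_error")
  }
  inp <- as_rows(x, model)
  scores <- sweep(inp$rows, 2L, model$mean) %*%
    model$basis[, seq_len(L), drop = FALSE]
  eb_scores(scores, inp$labels)
}

#' Score-matrix container
#'
#' @param scores K' x L numeric matrix of latent coordinates.
#' @param labels Length-K' class labels.
#' @return Object of class `eb_scores`.
#' @export
eb_scores <- function(scores, labels) {
  scores <- as.matrix(scores)
  structure(list(scores = scores, labels = factor(labels)),
            class = "eb_scores")
}

#' @export
print.eb_scores <- function(x, ...) {
  cat(sprintf("<eb_scores> %d subjects x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Reconstruct images from eigenbrain scores
#'
#' Inverse transform `X_hat = S W_L' + mean`: because the basis is
#' orthonormal the inverse of the projection is its transpose, and the
#' centering mean is re-added. At `L` equal to the rank, training images are
#' reproduced to numerical precision; at smaller `L` the squared Frobenius
#' reconstruction error equals the sum of squared discarded singular values
#' (the Eckart–Young optimum).
#'
#' @param scores An `eb_scores` object or a K' x L matrix.
#' @param model An `eigenbrain_model`.
#' @return K' x N numeric matrix of voxel rows.
#' @export
reconstruct <- function(scores, model) {
  stopifnot(inherits(model, "eigenbrain_model"))
  S <- if (inherits(scores, "eb_scores")) scores$scores else as.matrix(scores)
  L <- ncol(S)
  if (L > model$M) {
    abort(sprintf("score width %d exceeds model rank %d.", L, model$M),
          class = "eigensynth_dimension_error")
  }
  sweep(S %*% t(model$basis[, seq_len(L), drop = FALSE]), 2L, model$mean, `+`)
}

#' Clip negative voxel values to zero
#'
#' Radiotracer concentration cannot be negative; reconstruction through a
#' truncated basis can undershoot. Off by default at synthesis (keeps the
#' linear reconstruction exact); enable for export to viewers.
#'
#' @param rows Numeric matrix/vector.
#' @return Same shape with negative entries set to 0.
#' @export
clip_nonnegative <- function(rows) {
  rows[rows < 0] <- 0
  rows
}

#' Export eigenbrains as NIfTI volumes
#'
#' @param model An `eigenbrain_model`.
#' @param dir Output directory.
#' @param components Which components to export (default first `model$L`).
#' @return Paths written, invisibly.
#' @export
export_eigenbrains <- function(model, dir,
                               components = seq_len(model$L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(components))
  for (i in seq_along(components)) {
    j <- components[i]
    paths[i] <- file.path(dir, sprintf("eigenbrain_%03d.nii.gz", j))
    write_volume(unflatten(model$basis[, j], model$mask, model$geometry),
                 model$geometry, paths[i])
  }
  invisible(paths)
}

#' Scree plot of an eigenbrain model
#'
#' @param object An `eigenbrain_model`.
#' @param ... Unused.
#' @return A ggplot: variance explained per component.
#' @method autoplot eigenbrain_model
#' @export
autoplot.eigenbrain_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "component", y = "fraction of variance",
                  title = "Eigenbrain variance spectrum") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
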