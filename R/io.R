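#' Volume geometry
#'
#' Describes the grid a 3D brain volume lives on: the number of voxels per
#' axis and the affine mapping voxel indices to world (scanner/MNI)
#' millimetre coordinates. All volumes entering a dataset must share the same
#' geometry, since the whole pipeline assumes the images are spatially
#' co-registered.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix mapping homogeneous voxel indices to
#'   world coordinates. Must be invertible. Defaults to identity (1 mm
#'   isotropic, origin at the first voxel).
#' @param voxel_units Unit string, default `"mm"`.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(shape, affine = diag(4), voxel_units = "mm") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    abort("`shape` must be 3 positive integers.", class = "eigensynth_geometry_error")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.finite(det(affine)) ||
      abs(det(affine)) < .Machine$double.eps) {
    abort("`affine` must be an invertible 4x4 matrix.",
          class = "eigensynth_geometry_error")
  }
  structure(list(shape = shape, affine = affine, voxel_units = voxel_units),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %s voxels (%s)\n",
              paste(x$shape, collapse = "x"), x$voxel_units))
  invisible(x)
}

geometry_compatible <- function(a, b, tol = 1e-4) {
  if (!identical(a$shape, b$shape)) return(FALSE)
  scale <- pmax(abs(a$affine), abs(b$affine), 1)
  all(abs(a$affine - b$affine) / scale <= tol)
}

#' Construct a subjects-by-voxels dataset
#'
#' The central data container: a `K x N` matrix of in-mask voxel intensities
#' (one row per subject), per-subject class labels, the boolean mask that
#' selects the `N` voxels out of the full grid, and the shared geometry.
#'
#' Voxel linearization order is fixed and documented: in-mask voxels are
#' taken in R's native column-major (first-axis-fastest) array order, i.e.
#' the order returned by `which(mask)`. Two reads of the same files always
#' yield identical matrices.
#'
#' @param data K x N numeric matrix, no non-finite values.
#' @param labels Length-K class labels (coerced to factor).
#' @param mask Logical 3D array with `sum(mask) == N` and `dim(mask)`
#'   matching `geometry$shape`.
#' @param geometry A [volume_geometry()].
#' @param subject_ids Length-K character vector of unique subject ids.
#' @return An object of class `voxel_dataset` with fields `data`, `labels`,
#'   `mask`, `geometry`, `subject_ids` and (after [normalize_to_max()])
#'   `normalization`.
#' @export
voxel_dataset <- function(data, labels, mask, geometry, subject_ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) {
    abort("`data` contains non-finite values.", class = "eigensynth_data_error")
  }
  if (!is.logical(mask) || !identical(dim(mask), as.integer(geometry$shape))) {
    abort("`mask` must be a logical array matching the geometry shape.",
          class = "eigensynth_geometry_error")
  }
  if (ncol(data) != sum(mask)) {
    abort(sprintf("data has %d columns but the mask selects %d voxels.",
                  ncol(data), sum(mask)),
          class = "eigensynth_dimension_error")
  }
  if (length(labels) != nrow(data)) {
    abort("one label per subject (row) is required.",
          class = "eigensynth_label_error")
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subj_%03d", seq_len(nrow(data)))
  }
  rownames(data) <- subject_ids
  structure(list(data = data, labels = factor(labels), mask = mask,
                 geometry = geometry, subject_ids = as.character(subject_ids),
                 normalization = NULL),
            class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("<voxel_dataset> %d subjects x %d in-mask voxels (grid %s)\n",
              nrow(x$data), ncol(x$data), paste(x$geometry$shape, collapse = "x")))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.voxel_dataset <- function(x) dim(x$data)

#' Subset a dataset by subject
#'
#' @param dataset A [voxel_dataset()].
#' @param subjects Integer or logical index over subjects (rows).
#' @return A `voxel_dataset` with the selected subjects.
#' @export
subset_subjects <- function(dataset, subjects) {
  out <- dataset
  out$data <- dataset$data[subjects, , drop = FALSE]
  out$labels <- factor(dataset$labels[subjects])
  out$subject_ids <- dataset$subject_ids[subjects]
  if (!is.null(dataset$normalization)) {
    out$normalization <-
      dataset$normalization[match(out$subject_ids,
                                  dataset$normalization$subject_id), ]
  }
  out
}

#' Flatten a 3D volume to an in-mask row vector
#'
#' @param volume Numeric 3D array.
#' @param mask Logical 3D array of the same shape.
#' @return Numeric vector of length `sum(mask)`, in column-major
#'   (first-axis-fastest) order over the mask's true voxels.
#' @export
flatten_volume <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) {
    abort("volume and mask shapes differ.", class = "eigensynth_dimension_error")
  }
  as.double(volume[mask])
}

#' Expand an in-mask row vector back to a 3D volume
#'
#' Inverse of [flatten_volume()]: in-mask voxels receive the row values in
#' the documented column-major order; out-of-mask voxels are 0.
#'
#' @param row Numeric vector of length `sum(mask)`.
#' @param mask Logical 3D array.
#' @param geometry A [volume_geometry()] whose shape matches `mask`.
#' @return Numeric 3D array of shape `geometry$shape`.
#' @export
unflatten <- function(row, mask, geometry) {
  if (!identical(dim(mask), as.integer(geometry$shape))) {
    abort("mask shape does not match geometry.",
          class = "eigensynth_geometry_error")
  }
  if (length(row) != sum(mask)) {
    abort(sprintf("row length %d != %d in-mask voxels.",
                  length(row), sum(mask)),
          class = "eigensynth_dimension_error")
  }
  vol <- array(0, dim = geometry$shape)
  vol[mask] <- row
  vol
}

nifti_geometry <- function(img) {
  affine <- structure(RNifti::xform(img), code = NULL)
  volume_geometry(dim(img)[1:3], matrix(as.numeric(affine), 4, 4),
                  voxel_units = "mm")
}

#' Read a labelled NIfTI dataset
#'
#' Reads a set of spatially co-registered NIfTI-1 volumes plus a label table
#' and assembles the subjects-by-voxels matrix. All volumes must share shape
#' and affine (affines compared entrywise with relative tolerance 1e-4 —
#' registration itself is out of scope, only consistency is enforced).
#'
#' When no mask is given, an implicit mask of voxels that are strictly
#' positive in at least one subject is built (PET/SPECT backgrounds are
#' zero or near-zero); a message records that this rule was applied.
#'
#' @param label_table Path to a CSV/TSV file with header columns
#'   `subject_id,path,class`, or a data frame with those columns. Relative
#'   image paths are resolved against the table's directory.
#' @param image_paths Optional character vector of NIfTI paths overriding the
#'   table's `path` column (matched by position).
#' @param mask Optional path to a binary NIfTI mask (or a logical array).
#' @return A [voxel_dataset()].
#' @export
read_dataset <- function(label_table, image_paths = NULL, mask = NULL) {
  if (is.character(label_table)) {
    sep <- if (grepl("\\.tsv$", label_table, ignore.case = TRUE)) "\t" else ","
    tab <- read.csv(label_table, sep = sep, stringsAsFactors = FALSE)
    base_dir <- dirname(label_table)
  } else {
    tab <- as.data.frame(label_table)
    base_dir <- "."
  }
  need <- c("subject_id", "path", "class")
  if (!all(need %in% names(tab))) {
    abort(sprintf("label table must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "eigensynth_label_error")
  }
  paths <- image_paths %||% tab$path
  if (length(paths) != nrow(tab)) {
    abort("one image path per label row is required.",
          class = "eigensynth_label_error")
  }
  paths <- ifelse(file.exists(paths), paths, file.path(base_dir, paths))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("image file not found: %s", paths[which(missing)[1]]),
          class = "eigensynth_io_error")
  }
  vols <- lapply(paths, RNifti::readNifti)
  geoms <- lapply(vols, nifti_geometry)
  for (i in seq_along(geoms)) {
    if (!geometry_compatible(geoms[[1]], geoms[[i]])) {
      abort(sprintf("volume '%s' has incompatible shape/affine.", paths[i]),
            class = "eigensynth_geometry_error")
    }
  }
  geometry <- geoms[[1]]
  arrs <- lapply(vols, function(v) array(as.double(v), dim = geometry$shape))
  if (is.null(mask)) {
    m <- Reduce(`|`, lapply(arrs, function(a) a > 0))
    message("No mask supplied; using implicit any-subject-positive mask (",
            sum(m), " voxels).")
  } else if (is.character(mask)) {
    mimg <- RNifti::readNifti(mask)
    if (!geometry_compatible(nifti_geometry(mimg), geometry)) {
      abort(sprintf("mask '%s' has incompatible shape/affine.", mask),
            class = "eigensynth_geometry_error")
    }
    m <- array(as.double(mimg) > 0, dim = geometry$shape)
  } else {
    m <- array(as.logical(mask), dim = geometry$shape)
  }
  data <- do.call(rbind, lapply(arrs, function(a) as.double(a[m])))
  voxel_dataset(data, tab$class, m, geometry, subject_ids = tab$subject_id)
}

#' Write a 3D volume as NIfTI-1
#'
#' Values are stored as float32 (the standard for PET/SPECT derivatives);
#' in-memory computation stays at float64 throughout the package.
#'
#' @param volume Numeric 3D array.
#' @param geometry A [volume_geometry()]; its affine is written as the
#'   sform/qform.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, geometry, path) {
  if (!identical(dim(volume), as.integer(geometry$shape))) {
    abort("volume shape does not match geometry.",
          class = "eigensynth_dimension_error")
  }
  img <- RNifti::asNifti(array(volume, dim = geometry$shape),
                         datatype = "float")
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(geometry$affine, code = 2L))
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(sprintf("could not write '%s'.", path), class = "eigensynth_io_error")
  }
  invisible(path)
}

#' Write every subject of a dataset as NIfTI plus a manifest CSV
#'
#' @param dataset A [voxel_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Tibble manifest (subject_id, class, path), also written to
#'   `manifest.csv` in `dir`.
#' @export
write_dataset <- function(dataset, dir, prefix = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(dataset$data))
  for (k in seq_len(nrow(dataset$data))) {
    paths[k] <- file.path(dir, sprintf("%s_%s.nii.gz", prefix,
                                       dataset$subject_ids[k]))
    write_volume(unflatten(dataset$data[k, ], dataset$mask, dataset$geometry),
                 dataset$geometry, paths[k])
  }
  manifest <- tibble::tibble(subject_id = dataset$subject_ids,
                             class = as.character(dataset$labels),
                             path = paths)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
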