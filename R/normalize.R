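#' Normalization-to-the-maximum of voxel intensities
#'
#' Makes voxel values directly comparable across subjects by removing
#' per-subject global scale differences (drug uptake, exposure time, scanner
#' gain). Each subject's image `I` is divided by its own normalizer
#' `I_n`, the average of its top-fraction in-mask intensities:
#' `I' = I / I_n`. With the default `fraction = 0.03` this is the classic
#' "top 3%" rule used for FDG-PET and DaTSCAN.
#'
#' The top count is `ceiling(fraction * N)` with a minimum of one voxel;
#' selection is by count on the sorted intensities, so boundary ties are
#' resolved deterministically. After normalization the mean of each
#' subject's top-fraction voxels equals 1 exactly, which makes the
#' operation idempotent.
#'
#' @param dataset A [voxel_dataset()].
#' @param fraction Top fraction of in-mask voxels to average, in (0, 1].
#' @return The dataset with `data` rescaled row-wise and a `normalization`
#'   tibble (`subject_id`, `normalizer`, `fraction`) recording each
#'   subject's `I_n` in raw intensity units.
#' @export
normalize_to_max <- function(dataset, fraction = 0.03) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].", class = "eigensynth_value_error")
  }
  n_vox <- ncol(dataset$data)
  n_top <- max(1L, ceiling(fraction * n_vox))
  normalizers <- numeric(nrow(dataset$data))
  for (k in seq_len(nrow(dataset$data))) {
    vals <- dataset$data[k, ]
    if (!any(vals > 0)) {
      abort(sprintf("subject '%s' has no strictly positive in-mask voxel.",
                    dataset$subject_ids[k]),
            class = "eigensynth_normalization_error")
    }
    top <- sort(vals, decreasing = TRUE)[seq_len(n_top)]
    normalizers[k] <- mean(top)
    dataset$data[k, ] <- vals / normalizers[k]
  }
  dataset$normalization <- tibble::tibble(
    subject_id = dataset$subject_ids,
    normalizer = normalizers,
    fraction = fraction
  )
  dataset
}
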