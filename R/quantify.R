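## SUVr images, global SUVr, and the specific amyloid load SAbL obtained by
## native-space subtraction of the estimated NS map.

#' Compute an SUVr image
#'
#' Divides a PET volume by the mean uptake in the reference region (a region
#' devoid of specific amyloid binding), so that the reference mean of the
#' result is exactly 1.
#'
#' @param pet 3D array of PET uptake (any consistent units).
#' @param reference_mask logical 3D array, non-empty.
#' @return An object of class `sabl_suvr`: `data` (3D array, unitless) and
#'   `reference_mean` (scalar, raw PET units).
#' @export
compute_suvr <- function(pet, reference_mask) {
  stopifnot_shape(pet, reference_mask, "pet / reference mask")
  if (!any(reference_mask)) stop("reference mask is empty", call. = FALSE)
  r <- mean(pet[reference_mask])
  if (!is.finite(r) || r <= 0) {
    stop("non-positive mean PET uptake in the reference region", call. = FALSE)
  }
  structure(list(data = pet / r, reference_mean = r), class = "sabl_suvr")
}

#' Mean image intensity inside a region mask
#'
#' @param image 3D array.
#' @param mask logical 3D array, non-empty.
#' @return Scalar arithmetic mean over the masked voxels.
#' @export
roi_mean <- function(image, mask) {
  stopifnot_shape(image, mask, "image / mask")
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mean(image[mask])
}

#' Specific amyloid load (SAbL) by NS subtraction
#'
#' Subtracts the subject's estimated nonspecific-uptake map from the SUVr
#' image in native space. Locally negative voxels are retained (the scalar
#' SAbL is a mean and clipping would bias it).
#'
#' @param suvr an `sabl_suvr` (or a plain 3D SUVr array).
#' @param ns_estimate 3D array, NS estimate in SUVr units.
#' @param gm_mask logical 3D array of cortical grey matter, non-empty.
#' @return list with `specific_image` (3D array, SUVr units) and `sabl`
#'   (scalar mean of the specific image over `gm_mask`).
#' @export
compute_sabl <- function(suvr, ns_estimate, gm_mask) {
  data <- if (inherits(suvr, "sabl_suvr")) suvr$data else suvr
  stopifnot_shape(data, ns_estimate, "SUVr / NS estimate")
  stopifnot_shape(data, gm_mask, "SUVr / GM mask")
  if (!any(gm_mask)) stop("GM mask is empty", call. = FALSE)
  specific <- data - ns_estimate
  list(specific_image = specific, sabl = mean(specific[gm_mask]))
}

#' Select the lowest-SUVr training subset
#'
#' Returns the indices of the `n_select` subjects with the smallest global
#' SUVr, the selection rule used to assemble a training pool that exhibits
#' mainly nonspecific uptake. Ties are broken by ascending subject index.
#'
#' @param cohort_suvr_globals numeric vector of global SUVr values.
#' @param n_select number of subjects to select.
#' @return Integer indices, ordered by increasing SUVr.
#' @export
select_training_set <- function(cohort_suvr_globals, n_select) {
  if (n_select > length(cohort_suvr_globals)) {
    stop("n_select exceeds the cohort size", call. = FALSE)
  }
  ord <- order(cohort_suvr_globals, seq_along(cohort_suvr_globals))
  ord[seq_len(n_select)]
}
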