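## NIfTI-1 volume I/O and cohort serialization.

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `voxel_size` (mm per axis) and
#'   `affine` (4x4 voxel-to-world matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img),
       voxel_size = RNifti::pixdim(img),
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a NIfTI volume
#'
#' @param data numeric or logical 3D array (logical masks are written 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel size in mm per axis.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(2, 2, 2)) {
  if (is.logical(data)) data <- array(as.double(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask, checking its grid
#'
#' @param path NIfTI file with 0/1 voxels.
#' @param reference_shape expected grid dimensions, or `NULL` to skip the check.
#' @return Logical 3D array.
#' @export
read_mask <- function(path, reference_shape = NULL) {
  v <- read_volume(path)
  if (!is.null(reference_shape) && !identical(dim(v$data), as.integer(reference_shape))) {
    stop(sprintf("mask grid %s does not match reference grid %s (%s)",
                 paste(dim(v$data), collapse = "x"),
                 paste(reference_shape, collapse = "x"), path), call. = FALSE)
  }
  v$data > 0.5
}

#' Write a phantom cohort to disk
#'
#' One directory per subject containing `t1.nii.gz`, `flair.nii.gz`,
#' `pet.nii.gz` and one mask file per region, plus a cohort-level CSV with
#' the ground-truth burden, lesion counts and covariates.
#'
#' @param cohort an `sabl_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$config$voxel_size_mm
  for (i in seq_along(cohort$subjects)) {
    sd <- file.path(dir, sprintf("sub-%03d", i))
    dir.create(sd, showWarnings = FALSE)
    v <- cohort$subjects[[i]]$volumes
    write_volume(v$t1, file.path(sd, "t1.nii.gz"), vs)
    write_volume(v$flair, file.path(sd, "flair.nii.gz"), vs)
    write_volume(v$pet, file.path(sd, "pet.nii.gz"), vs)
    for (mn in names(v$masks)) {
      write_volume(v$masks[[mn]], file.path(sd, sprintf("mask_%s.nii.gz", mn)), vs)
    }
  }
  utils::write.csv(cohort_table(cohort), file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read one subject directory written by [write_cohort()]
#'
#' @param dir subject directory.
#' @return An `sabl_subject`-shaped list (`t1`, `flair`, `pet`, `masks`).
#' @export
read_subject <- function(dir) {
  t1 <- read_volume(file.path(dir, "t1.nii.gz"))
  shape <- dim(t1$data)
  masks <- lapply(c(wb = "wb", gm = "gm", wm = "wm", reference = "reference"),
                  function(mn) read_mask(file.path(dir, sprintf("mask_%s.nii.gz", mn)), shape))
  structure(list(
    t1 = t1$data,
    flair = read_volume(file.path(dir, "flair.nii.gz"))$data,
    pet = read_volume(file.path(dir, "pet.nii.gz"))$data,
    masks = masks,
    voxel_size_mm = t1$voxel_size
  ), class = "sabl_subject")
}
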