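# NIfTI import/export for dose grids and structure masks.
# Doses are stored as floating-point Gy, masks as 0/1. Fraction counts and
# frame identifiers are not part of the NIfTI header, so they are supplied by
# the caller on read.

#' Read and write dose grids and masks as NIfTI volumes
#'
#' @param grid A [dose_grid()] or `eqd2_grid` to write.
#' @param mask A [structure_mask()] to write.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param n_fractions Fraction count to attach to the grid on read.
#' @param frame_id Registration-frame identifier to attach on read.
#' @param alpha_beta For `read_eqd2_nifti`: the alpha/beta the stored values
#'   were computed with.
#' @param name Structure label to attach to the mask on read.
#' @return The read functions return a `dose_grid`, `eqd2_grid` or
#'   `structure_mask`; the write functions return `path` invisibly.
#' @name nifti_io
NULL

write_volume_nifti <- function(values, spacing, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname nifti_io
#' @export
write_dose_nifti <- function(grid, path) {
  stopifnot(inherits(grid, c("dose_grid", "eqd2_grid")))
  write_volume_nifti(grid$values, grid$spacing, path)
}

#' @rdname nifti_io
#' @export
read_dose_nifti <- function(path, n_fractions, frame_id = "frame-1") {
  v <- read_volume_nifti(path)
  dose_grid(v$values, v$spacing, n_fractions, frame_id)
}

#' @rdname nifti_io
#' @export
read_eqd2_nifti <- function(path, alpha_beta = 3, frame_id = "frame-1") {
  v <- read_volume_nifti(path)
  eqd2_grid(v$values, v$spacing, frame_id, alpha_beta)
}

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_volume_nifti(array(as.integer(mask$values), dim = dim(mask$values)),
                     mask$spacing, path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path, name = "structure", frame_id = "frame-1") {
  v <- read_volume_nifti(path)
  structure_mask(v$values != 0, v$spacing, frame_id = frame_id, name = name)
}
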