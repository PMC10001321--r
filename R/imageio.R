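# NIfTI I/O for CT volumes and ROI masks, and ROI pixel extraction.

#' Construct a CT volume
#'
#' @param voxels 2D or 3D numeric array of HU values (a 2D array is
#'   promoted to a single-slice volume); must be finite.
#' @param spacing Voxel spacing in mm, length 3, strictly positive.
#' @return A `ct_volume` with fields `voxels` (3D array, axial slice =
#'   last axis) and `spacing`.
#' @export
ct_volume <- function(voxels, spacing) {
  if (length(dim(voxels)) == 2) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3) stopf("voxels must be a 2D or 3D array")
  if (!all(is.finite(voxels))) stopf("HU values must be finite")
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "ct_volume")
}

#' Write a CT volume (or label mask) to NIfTI
#'
#' @param volume A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, d, 1L, 1L, 1L, 1L),
    pixdim = c(0, volume$spacing, 0, 0, 0, 0)))
  RNifti::writeNifti(RNifti::asNifti(volume$voxels, reference = hdr), path)
  invisible(path)
}

#' Read a CT volume from NIfTI
#'
#' Single-slice files stored as 2D NIfTI are promoted back to a 3D array
#' with third dimension 1; the slice spacing is recovered from the
#' header's third pixdim. Fails loudly on non-positive spacing.
#'
#' @param path NIfTI file path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("unreadable NIfTI '%s': %s",
                                            path, conditionMessage(e)))
  hdr <- RNifti::niftiHeader(path)
  voxels <- array(as.vector(img), dim(img))   # plain array, no image attrs
  spacing <- abs(hdr$pixdim[2:4])
  if (length(dim(voxels)) == 2) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3) stopf("'%s' is not a 2D/3D volume", path)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("'%s' has missing or non-positive voxel spacing", path)
  ct_volume(voxels, spacing)
}

#' Define a region of interest on a volume grid
#'
#' @param region_name Region label.
#' @param mask Logical array congruent with the target volume grid.
#' @param slice_indices 1 to 3 axial slice indices on which the ROI lives.
#' @return An `roi_def`.
#' @export
roi_def <- function(region_name, mask, slice_indices) {
  if (length(dim(mask)) == 2) dim(mask) <- c(dim(mask), 1L)
  if (!is.logical(mask) || length(dim(mask)) != 3)
    stopf("mask must be a logical 2D/3D array")
  n <- length(slice_indices)
  if (n < 1 || n > 3) stopf("slice_indices must have 1 to 3 entries")
  if (any(slice_indices < 1 | slice_indices > dim(mask)[3]))
    stopf("slice index out of range")
  if (!any(mask[, , slice_indices]))
    stopf("empty ROI: mask has no voxels on the listed slices")
  structure(list(region_name = region_name, mask = mask,
                 slice_indices = as.integer(slice_indices)),
            class = "roi_def")
}

#' Build an ROI from an integer label mask
#'
#' @param mask_volume `ct_volume` holding integer labels (0 = background).
#' @param label Label value selecting the region.
#' @param region_name Name to attach.
#' @return An `roi_def` listing every slice on which the label appears.
#' @export
roi_from_mask <- function(mask_volume, label, region_name) {
  stopifnot(inherits(mask_volume, "ct_volume"))
  m <- mask_volume$voxels == label
  slices <- which(apply(m, 3, any))
  if (!length(slices)) stopf("label %s absent from mask", label)
  roi_def(region_name, m, slices)
}

#' Extract the HU values of an ROI
#'
#' Pools the masked voxels of every listed slice into one vector, in a
#' fixed deterministic order (column-major within slice, slices in listed
#' order).
#'
#' @param volume A [ct_volume()].
#' @param roi An [roi_def()]; grid must match the volume's within 1e-6.
#' @return Numeric HU vector with length equal to the mask cardinality
#'   on the listed slices.
#' @export
extract_roi_pixels <- function(volume, roi) {
  stopifnot(inherits(volume, "ct_volume"), inherits(roi, "roi_def"))
  if (!identical(dim(volume$voxels), dim(roi$mask)))
    stopf("geometry mismatch: volume grid %s vs mask grid %s",
          paste(dim(volume$voxels), collapse = "x"),
          paste(dim(roi$mask), collapse = "x"))
  out <- unlist(lapply(roi$slice_indices, function(s)
    volume$voxels[, , s][roi$mask[, , s]]), use.names = FALSE)
  if (!length(out)) stopf("empty ROI")
  out
}
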