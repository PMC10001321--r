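# Percent fat within a regional ROI by Hounsfield-unit thresholding.

#' Fat attenuation window
#'
#' Both ends inclusive; defaults to the conventional CT fat window of
#' -190 to 0 HU.
#' @param lo Lower bound (HU). @param hi Upper bound (HU); must exceed `lo`.
#' @return A `fat_threshold`.
#' @export
fat_threshold <- function(lo = -190, hi = 0) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stopf("fat threshold requires lo < hi")
  structure(list(lo = lo, hi = hi), class = "fat_threshold")
}

#' Percent fat of a pixel vector
#'
#' `100 * (# pixels with lo <= HU <= hi) / (# pixels)`. Pixel counting
#' stands in for the surface-area ratio, which is equivalent under
#' uniform pixel spacing. Boundary pixels at exactly `lo` or `hi` count
#' as fat.
#'
#' @param pixels Non-empty HU vector.
#' @param threshold A [fat_threshold()].
#' @return Percent in \[0, 100\].
#' @export
fat_fraction <- function(pixels, threshold = fat_threshold()) {
  if (!length(pixels)) stopf("empty ROI: no pixels supplied")
  100 * mean(pixels >= threshold$lo & pixels <= threshold$hi)
}

#' Per-region fat percents for a cohort
#'
#' Resolves each manifest record to its image and mask, pools the ROI
#' pixels and computes the fat percent. Regions whose mask label is
#' absent are recorded as `NA` with `absent = TRUE`, never as zero.
#'
#' @param manifest A `cohort_manifest`.
#' @param base_dir Directory the manifest's relative paths resolve in.
#' @param threshold A [fat_threshold()].
#' @return data.frame: patient_id, region_name, fat_pct, absent.
#' @export
regional_fat_table <- function(manifest, base_dir,
                               threshold = fat_threshold()) {
  rec <- manifest$records
  cache <- new.env(parent = emptyenv())
  read_cached <- function(p) {
    key <- paste0("f", p)
    if (is.null(cache[[key]])) cache[[key]] <- read_volume(file.path(base_dir, p))
    cache[[key]]
  }
  out <- lapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    vol <- read_cached(r$image_path)
    msk <- read_cached(r$mask_path)
    present <- any(msk$voxels == r$region_label)
    fp <- if (present) {
      roi <- roi_from_mask(msk, r$region_label, r$region_name)
      fat_fraction(extract_roi_pixels(vol, roi), threshold)
    } else NA_real_
    data.frame(patient_id = r$patient_id, region_name = r$region_name,
               fat_pct = fp, absent = !present, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
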