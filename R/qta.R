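# Filtration-histogram texture analysis: Laplacian-of-Gaussian band-pass
# filtering per axial slice, then six first-order statistics of the masked
# (filtered) pixel histogram.

# 1D convolution along rows (axis = 1) or columns (axis = 2) with reflect
# padding, implemented as shift-and-add so each kernel tap is one vectorised
# matrix operation.
conv1d_reflect <- function(img, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  n <- dim(img)[axis]
  if (r >= n) stopf("image too small for a kernel of radius %d", r)
  # reflect indices: for i in 1-r .. n+r map to mirrored interior index
  idx <- seq.int(1L - r, n + r)
  idx <- ifelse(idx < 1L, 1L - idx + 1L, idx)      # reflect about edge (no repeat)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  padded <- if (axis == 1) img[idx, , drop = FALSE] else img[, idx, drop = FALSE]
  out <- array(0, dim(img))
  for (k in seq_along(kernel)) {
    off <- k - 1L
    sl <- if (axis == 1) padded[seq.int(1L + off, dim(img)[1] + off), , drop = FALSE]
          else padded[, seq.int(1L + off, dim(img)[2] + off), drop = FALSE]
    out <- out + kernel[k] * sl
  }
  out
}

# Sampled 1D Gaussian and its second derivative, scaled by the pixel pitch so
# that discrete convolution approximates the continuous integral (units: the
# LoG response carries 1/mm^2).
gauss_kernels_1d <- function(sigma_mm, dx_mm, radius_sigma = 4.5) {
  r <- max(2L, as.integer(ceiling(radius_sigma * sigma_mm / dx_mm)))
  x <- seq.int(-r, r) * dx_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sqrt(2 * pi) * sigma_mm)
  gxx <- g * (x^2 - sigma_mm^2) / sigma_mm^4
  list(g = g * dx_mm, gxx = gxx * dx_mm, radius = r)
}

#' Laplacian-of-Gaussian band-pass filter at one spatial scaling factor
#'
#' SSF 0 is the identity (no filtering). For SSF > 0 the response is the
#' 2D Laplacian of the Gaussian-smoothed slice, with Gaussian
#' `sigma (mm) = ssf / (2 * sqrt(2))` so that the zero-crossing diameter
#' of the LoG equals `ssf` mm. Computed separably
#' (`gxx (x) g + g (x) gyy`) with reflect padding; the sampled kernels are
#' scaled by the pixel pitch, so the response approximates the continuous
#' convolution and carries units of HU/mm^2.
#'
#' @param slice_image 2D numeric matrix (HU), at least 5x5.
#' @param ssf Spatial scaling factor in mm; 0 or positive.
#' @param spacing In-plane pixel spacing (mm), length 1 or 2.
#' @param sigma_per_ssf Scale mapping, sigma = sigma_per_ssf * ssf;
#'   default `1/(2*sqrt(2))`.
#' @return Filtered matrix, same dimensions as the input.
#' @export
log_filter <- function(slice_image, ssf, spacing,
                       sigma_per_ssf = 1 / (2 * sqrt(2))) {
  if (!is.matrix(slice_image)) stopf("slice_image must be a matrix")
  if (any(dim(slice_image) < 5)) stopf("slice must be at least 5x5")
  if (!is.numeric(ssf) || length(ssf) != 1 || ssf < 0)
    stopf("ssf must be a single non-negative number")
  if (any(spacing <= 0)) stopf("spacing must be positive")
  if (ssf == 0) return(slice_image)
  sp <- rep_len(spacing, 2)
  sigma <- sigma_per_ssf * ssf
  kx <- gauss_kernels_1d(sigma, sp[1])
  ky <- gauss_kernels_1d(sigma, sp[2])
  dxx <- conv1d_reflect(conv1d_reflect(slice_image, kx$gxx, 1), ky$g, 2)
  dyy <- conv1d_reflect(conv1d_reflect(slice_image, kx$g, 1), ky$gxx, 2)
  dxx + dyy
}

#' Six first-order statistics of a pixel vector
#'
#' mean; sample SD (n-1); mean of strictly positive pixels (MPP, 0 with
#' `mpp_defined = FALSE` attribute when no pixel is positive); Fisher
#' moment skewness; excess kurtosis (normal = 0); Shannon entropy in bits
#' of the `n_bins`-bin histogram between the vector min and max.
#' Constant vectors take the degenerate conventions sd = skewness =
#' kurtosis = entropy = 0.
#'
#' @param pixels Non-empty numeric vector.
#' @param n_bins Histogram bins for entropy (default 64).
#' @return Named numeric vector `mean`, `sd`, `mpp`, `skewness`,
#'   `kurtosis`, `entropy`.
#' @export
first_order_stats <- function(pixels, n_bins = 64) {
  if (!length(pixels)) stopf("empty ROI: no pixels supplied")
  if (!all(is.finite(pixels))) stopf("pixels must be finite")
  n <- length(pixels)
  m <- mean(pixels)
  dev <- pixels - m
  m2 <- mean(dev^2)
  s <- if (n > 1) sqrt(sum(dev^2) / (n - 1)) else 0
  pos <- pixels[pixels > 0]
  mpp <- if (length(pos)) mean(pos) else 0
  if (m2 > 0) {
    skew <- mean(dev^3) / m2^1.5
    kurt <- mean(dev^4) / m2^2 - 3
    ent <- bin_entropy(pixels, n_bins)
  } else {
    skew <- 0; kurt <- 0; ent <- 0
  }
  out <- c(mean = m, sd = s, mpp = mpp, skewness = skew, kurtosis = kurt,
           entropy = ent)
  attr(out, "mpp_defined") <- length(pos) > 0
  out
}

# Shannon entropy (bits) of the equal-width histogram between min and max;
# the top edge is closed so the maximum lands in the last bin.
bin_entropy <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(0)
  bin <- pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  p <- tabulate(bin, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the filtration-histogram feature vector of one ROI
#'
#' For each SSF level, filters every listed slice, pools the masked
#' filtered values, and computes the six first-order statistics; the
#' mask is applied after filtering so the filter sees surrounding
#' tissue. Default SSF set {0, 2, 3, 4, 5, 6} yields 36 named values.
#'
#' @param volume A [ct_volume()].
#' @param roi An [roi_def()].
#' @param ssf_set Non-empty numeric vector of SSF levels (mm).
#' @param n_bins Entropy histogram bins.
#' @param sigma_per_ssf Passed to [log_filter()].
#' @return Named numeric vector of `6 * length(ssf_set)` entries
#'   `ssf<k>_<stat>`.
#' @export
extract_qta <- function(volume, roi, ssf_set = c(0, 2, 3, 4, 5, 6),
                        n_bins = 64, sigma_per_ssf = 1 / (2 * sqrt(2))) {
  if (!length(ssf_set)) stopf("ssf_set must be non-empty")
  out <- numeric(0)
  for (k in ssf_set) {
    vals <- unlist(lapply(roi$slice_indices, function(s) {
      f <- log_filter(volume$voxels[, , s], k, volume$spacing[1:2],
                      sigma_per_ssf)
      f[roi$mask[, , s]]
    }), use.names = FALSE)
    st <- first_order_stats(vals, n_bins)
    names(st) <- sprintf("ssf%g_%s", k, names(st))
    out <- c(out, st)
  }
  out
}
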