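#' First-order intensity features
#'
#' The 14 histogram/intensity statistics of the inventory, computed over the
#' in-mask voxels: mean, median, minimum, maximum, range, interquartile
#' range, variance (population), skewness, kurtosis, energy, entropy,
#' uniformity, robust mean absolute deviation, and root-mean-squared.
#' Entropy and uniformity are computed on a fixed 32-bin equal-width
#' discretization of the in-mask range. Zero-variance regions use the
#' conventions skewness = kurtosis = 0, entropy = 0, uniformity = 1.
#'
#' @param volume an [image_volume()].
#' @param mask a nonempty [voxel_mask()] on the same grid.
#' @param entropy_bins bin count for the entropy/uniformity histogram.
#' @return Named numeric vector of length 14.
#' @export
first_order_features <- function(volume, mask, entropy_bins = 32) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voxel_mask"))
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("volume and mask grids disagree")
  if (!any(mask$values)) stop("empty mask")
  x <- volume$values[mask$values]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0

  if (max(x) > min(x)) {
    w <- (max(x) - min(x)) / entropy_bins
    lev <- pmin(floor((x - min(x)) / w) + 1, entropy_bins)
    p <- tabulate(lev, nbins = entropy_bins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
  } else {
    entropy <- 0
    uniformity <- 1
  }
  qs <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  xr <- x[x >= qs[1] & x <= qs[5]]
  rmad <- mean(abs(xr - mean(xr)))

  c(fo_mean = mu,
    fo_median = qs[3],
    fo_minimum = min(x),
    fo_maximum = max(x),
    fo_range = max(x) - min(x),
    fo_iqr = qs[4] - qs[2],
    fo_variance = m2,
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_energy = sum(x^2),
    fo_entropy = entropy,
    fo_uniformity = uniformity,
    fo_rmad = rmad,
    fo_rms = sqrt(mean(x^2)))
}
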