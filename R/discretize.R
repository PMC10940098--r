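#' Discretize in-mask intensities to integer gray levels
#'
#' Fixed-bin-count, equal-width discretization over the in-mask intensity
#' range: the span `[min, max]` is split into `bins` equal bins and each voxel
#' is assigned its bin index `1..bins`. A constant region maps every voxel to
#' level 1. Fixed bin count (rather than fixed bin width) makes the texture
#' features invariant to affine intensity rescaling of the input.
#'
#' @param volume an [image_volume()].
#' @param mask a nonempty [voxel_mask()] on the same grid.
#' @param bins number of gray levels (>= 2).
#' @return A `quantized_region`: list with `levels` (3D integer array, 0
#'   outside the mask), `G` (bin count) and the region's voxel count.
#' @export
discretize <- function(volume, mask, bins) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voxel_mask"))
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("volume and mask grids disagree")
  if (bins < 2) stop("`bins` must be >= 2")
  m <- mask$values
  if (!any(m)) stop("empty mask")
  x <- volume$values[m]
  lo <- min(x); hi <- max(x)
  lev <- integer(length(x))
  if (hi > lo) {
    w <- (hi - lo) / bins
    lev <- pmin(as.integer(floor((x - lo) / w)) + 1L, as.integer(bins))
  } else {
    lev[] <- 1L
  }
  q <- array(0L, dim(m))
  q[m] <- lev
  structure(list(levels = q, G = as.integer(bins), n_voxels = sum(m),
                 spacing = mask$spacing),
            class = "quantized_region")
}
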