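#' Image volume and voxel mask containers
#'
#' Light containers for 3D imaging data with physical voxel geometry. An
#' `image_volume` holds a real-valued 3D grid; a `voxel_mask` holds a logical
#' 3D grid. Both carry `spacing` (mm per voxel along each array axis) and
#' `origin` (mm position of the center of voxel `[1,1,1]`). Axis order is the
#' R array order; all morphology is computed in mm via the spacing, so the
#' convention is internal only.
#'
#' @param values 3D numeric array (`image_volume`) or array coercible to
#'   logical (`voxel_mask`).
#' @param spacing positive length-3 numeric, mm per voxel.
#' @param origin length-3 numeric, mm.
#' @return An object of class `image_volume` or `voxel_mask`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (length(values) == 0L) stop("empty image grid")
  if (!all(is.finite(spacing)) || any(spacing <= 0) || length(spacing) != 3L)
    stop("`spacing` must be 3 positive reals")
  if (!all(is.finite(values))) stop("image intensities must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
voxel_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (length(values) == 0L) stop("empty mask grid")
  if (!all(is.finite(spacing)) || any(spacing <= 0) || length(spacing) != 3L)
    stop("`spacing` must be 3 positive reals")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must be 0/1")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> dim", paste(dim(x$values), collapse = "x"),
      " spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> dim", paste(dim(x$values), collapse = "x"),
      " spacing", paste(signif(x$spacing, 4), collapse = "x"),
      "mm  foreground", sum(x$values), "voxels\n")
  invisible(x)
}

n_voxels <- function(mask) sum(mask$values)

voxel_volume_mm3 <- function(x) prod(x$spacing)

# mm coordinates (voxel centers) of the mask foreground, n x 3 matrix
mask_coords_mm <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Digital ellipsoid and sphere masks
#'
#' Build a binary mask of the voxels whose centers fall inside an ellipsoid
#' (inclusive boundary), centered in a grid padded by `margin_mm` on all sides.
#' Used both by the phantom generator and by geometry tests against analytic
#' volumes.
#'
#' @param semi_axes length-3 numeric, ellipsoid semi-axes in mm.
#' @param spacing voxel spacing in mm.
#' @param margin_mm padding around the ellipsoid in mm.
#' @return A [voxel_mask()].
#' @export
ellipsoid_mask <- function(semi_axes, spacing = c(1, 1, 1), margin_mm = 6) {
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3)
  if (any(semi_axes / spacing < 3)) stop("degenerate geometry: semi-axes < 3 voxels")
  dims <- 2L * ceiling((semi_axes + margin_mm) / spacing) + 1L
  ctr <- (dims - 1) / 2 * spacing
  ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - 1) * spacing[k] - ctr[k]) / semi_axes[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  voxel_mask(d2 <= 1, spacing = spacing)
}

#' @rdname ellipsoid_mask
#' @param radius_mm sphere radius in mm.
#' @export
sphere_mask <- function(radius_mm, spacing = c(1, 1, 1), margin_mm = 6) {
  ellipsoid_mask(rep(radius_mm, 3), spacing = spacing, margin_mm = margin_mm)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti that carry the voxel spacing through the NIfTI
#' pixdim field. Masks are written as 0/1 integer volumes.
#'
#' @param x an [image_volume()] or [voxel_mask()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @export
write_volume_nifti <- function(x, path) {
  vals <- if (inherits(x, "voxel_mask")) array(as.integer(x$values), dim(x$values)) else x$values
  img <- RNifti::asNifti(vals, reference = NULL)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param mask logical; read as a [voxel_mask()] instead of an [image_volume()].
#' @export
read_volume_nifti <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vals <- array(as.numeric(img), dim(img)[1:3])
  if (mask) voxel_mask(vals != 0, spacing = sp) else image_volume(vals, spacing = sp)
}

# Euclidean distance (mm) from every voxel center to the nearest foreground
# voxel center of `mask`. Infinite where the mask is empty.
distance_to_mask <- function(mask) {
  d2 <- .edt3d_sq(as.logical(mask$values), dim(mask$values), mask$spacing)
  array(sqrt(d2), dim(mask$values))
}
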