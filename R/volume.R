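#' Image volume and lesion mask containers
#'
#' Lightweight containers for a 3D scalar grid in Hounsfield units (HU) and an
#' aligned binary lesion mask. Both carry the voxel spacing in mm per axis;
#' voxel index `(i, j, k)` sits at physical position `(i - 1, j - 1, k - 1) *
#' spacing` mm. These are the units every filter and shape feature works in.
#'
#' @param voxels 3D numeric array (HU) or, for masks, anything coercible to a
#'   3D logical/0-1 array.
#' @param spacing numeric length-3, voxel edge lengths in mm (x, y, z); all > 0.
#' @return An object of class `image_volume` or `lesion_mask`: a list with
#'   elements `voxels` (array) and `spacing` (numeric(3)).
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive mm values")
  }
  structure(list(voxels = voxels, spacing = spacing), class = "image_volume")
}

#' @rdname image_volume
#' @export
lesion_mask <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "integer"
  if (!all(voxels %in% c(0L, 1L))) stop("mask voxels must be binary (0/1)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive mm values")
  }
  structure(list(voxels = voxels, spacing = spacing), class = "lesion_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "lesion_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    stop("volume and mask grids differ in shape")
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-8) {
    stop("volume and mask voxel spacings differ")
  }
  invisible(TRUE)
}

#' Physical volume of a mask in cm^3
#'
#' Voxel count times voxel volume, converted from mm^3 to cm^3.
#' @param mask a [lesion_mask()].
#' @return scalar, cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti keeping the container contract (array + spacing).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x an `image_volume` or `lesion_mask`.
#' @return `read_volume`/`read_mask` return the container; writers return the
#'   path invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_mask(as.array(img) > 0.5, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- internal filtering helpers -------------------------------------------

# separable 3D filtering, kernel list per axis (NULL = skip axis)
# boundary: "symmetric", "nearest", "periodic"
conv3d_sep <- function(arr, kernels, origins = NULL, boundary = "symmetric") {
  bnd <- match(boundary, c("symmetric", "nearest", "periodic")) - 1L
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    k <- kernels[[ax]]
    if (is.null(k)) next
    org <- if (is.null(origins)) (length(k) - 1L) %/% 2L else origins[[ax]]
    out <- conv_axis_cpp(as.numeric(out), as.integer(d), as.numeric(k),
                         as.integer(org), ax - 1L, bnd)
  }
  array(out, d)
}

# sampled Gaussian kernel, sigma in voxels, truncated at `truncate` sigmas
gaussian_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# smooth an array with an isotropic-in-mm Gaussian given voxel spacing
gaussian_smooth <- function(arr, sigma_mm, spacing, boundary = "nearest",
                            truncate = 4) {
  ks <- lapply(1:3, function(ax) gaussian_kernel(sigma_mm / spacing[ax], truncate))
  conv3d_sep(arr, ks, boundary = boundary)
}

# bounding box of a mask array, padded by `margin` voxels, clipped to the grid
mask_bbox <- function(mask_arr, margin = 0L) {
  idx <- which(mask_arr > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(mask_arr))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_to_bbox <- function(arr, bbox) {
  arr[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2], bbox$lo[3]:bbox$hi[3],
      drop = FALSE]
}
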