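#' @keywords internal
#' @name coif1
#' @noRd
NULL

# Coiflet-1 analysis filters (orthonormal, 6 taps).
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

# resample one axis of a 3D array (cubic B-spline prefilter + evaluation,
# whole-point mirror boundary; degree 1 = linear); returns the new array
resample_axis <- function(arr, axis, s_in, s_out, degree = 3L) {
  out <- resample_axis_cpp(as.numeric(arr), as.integer(dim(arr)),
                           as.integer(axis - 1L), s_in, s_out,
                           as.integer(degree))
  array(out, attr(out, "dim"))
}

#' Resample a volume and mask to isotropic spacing
#'
#' The image is interpolated with a cubic B-spline (exact at the original
#' sample locations, so an already-isotropic input is returned unchanged up to
#' numerical round-off). The binary mask is interpolated linearly and
#' re-thresholded at 0.5, which preserves lesion volume better than
#' nearest-neighbour when going from thick slices to the isotropic grid. The
#' physical extent of the grid is preserved to within one voxel.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [lesion_mask()], or `NULL`.
#' @param new_spacing target spacing in mm, default `c(1, 1, 1)`.
#' @param mask_interpolation `"linear"` (threshold 0.5) or `"nearest"`.
#' @return list with elements `volume` and (if given) `mask` on the new grid.
#' @export
resample_isotropic <- function(volume, mask = NULL, new_spacing = c(1, 1, 1),
                               mask_interpolation = c("linear", "nearest")) {
  stopifnot(inherits(volume, "image_volume"))
  mask_interpolation <- match.arg(mask_interpolation)
  if (!is.null(mask)) check_aligned(volume, mask)
  arr <- volume$voxels
  for (ax in 1:3) {
    arr <- resample_axis(arr, ax, volume$spacing[ax], new_spacing[ax], 3L)
  }
  out <- list(volume = image_volume(arr, new_spacing))
  if (!is.null(mask)) {
    m <- mask$voxels
    storage.mode(m) <- "double"
    deg <- if (mask_interpolation == "linear") 1L else 0L
    for (ax in 1:3) {
      if (deg == 1L) {
        m <- resample_axis(m, ax, mask$spacing[ax], new_spacing[ax], 1L)
      } else {
        # nearest: snap output positions to the closest input sample
        d <- dim(m); n_in <- d[ax]
        n_out <- floor((n_in - 1) * mask$spacing[ax] / new_spacing[ax] + 1e-9) + 1L
        t_out <- round((seq_len(n_out) - 1) * new_spacing[ax] / mask$spacing[ax]) + 1L
        t_out <- pmin(pmax(t_out, 1L), n_in)
        m <- switch(ax, m[t_out, , , drop = FALSE], m[, t_out, , drop = FALSE],
                    m[, , t_out, drop = FALSE])
      }
    }
    out$mask <- lesion_mask(m >= 0.5, new_spacing)
  }
  out
}

#' Re-segment a lesion mask to a HU density range
#'
#' Restricts the mask to voxels whose image value lies in `[lo, hi]` HU
#' (defaults 1--200), removing calcification-level and fluid/air-level voxels
#' from the region of interest. All features, including shape features, are
#' computed on the re-segmented mask.
#'
#' @inheritParams resample_isotropic
#' @param lo,hi inclusive HU bounds; `lo < hi`.
#' @return A [lesion_mask()]. If no voxel survives, the mask carries
#'   `attr(, "empty") = TRUE` and the patient should be excluded upstream.
#' @export
resegment_mask <- function(volume, mask, lo = 1, hi = 200) {
  check_aligned(volume, mask)
  if (!(lo < hi)) stop("`lo` must be smaller than `hi`")
  keep <- mask$voxels == 1L & volume$voxels >= lo & volume$voxels <= hi
  out <- lesion_mask(keep, mask$spacing)
  if (sum(out$voxels) == 0L) attr(out, "empty") <- TRUE
  out
}

#' Single-level undecimated coiflet-1 wavelet bank
#'
#' Applies the orthonormal coiflet-1 analysis filters without decimation
#' (stationary transform) along each axis, with symmetric boundary extension,
#' yielding the eight sub-bands `LLL ... HHH`. Letters give the filter (L =
#' low-pass, H = high-pass) applied along the x, y and z axis in that order;
#' every sub-band keeps the input grid so the lesion mask applies unchanged.
#'
#' With `decimated = TRUE` a single-level decimated transform with periodic
#' boundary is computed instead (each axis halved; axis lengths must be even).
#' Because coiflet-1 is orthonormal, the summed energy of the eight decimated
#' sub-bands equals the input energy; this mode exists as a filter-coefficient
#' sanity check, not for feature extraction.
#'
#' @param volume an [image_volume()] (minimum extent 6 voxels per axis in the
#'   undecimated mode).
#' @param decimated logical, see above.
#' @return Named list of eight `image_volume`s, names `wavelet-LLL` ...
#'   `wavelet-HHH`.
#' @export
wavelet_bank <- function(volume, decimated = FALSE) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$voxels)
  if (!decimated && any(d < 6L)) {
    stop(sprintf("grid %s too small for the 6-tap coiflet-1 filters; need >= 6 per axis",
                 paste(d, collapse = "x")))
  }
  if (decimated && any(d %% 2L != 0L)) {
    stop("decimated mode requires even axis lengths")
  }
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  if (!decimated) {
    # shared-partial separable filtering: x pass (2), xy passes (4), xyz (8)
    conv1 <- function(arr, ch, ax) {
      ks <- list(NULL, NULL, NULL)
      ks[[ax]] <- if (ch == "L") COIF1_LO else COIF1_HI
      conv3d_sep(arr, ks, origins = list(2L, 2L, 2L), boundary = "symmetric")
    }
    part_x <- lapply(c(L = "L", H = "H"), conv1, arr = volume$voxels, ax = 1L)
    part_xy <- list()
    for (cx in c("L", "H")) for (cy in c("L", "H")) {
      part_xy[[paste0(cx, cy)]] <- conv1(part_x[[cx]], cy, 2L)
    }
    out <- lapply(labels, function(lab) {
      l <- strsplit(lab, "")[[1]]
      image_volume(conv1(part_xy[[paste0(l[1], l[2])]], l[3], 3L),
                   volume$spacing)
    })
  } else {
    out <- lapply(labels, function(lab) {
      l <- strsplit(lab, "")[[1]]
      arr <- volume$voxels
      for (ax in 1:3) {
        k <- if (l[ax] == "L") COIF1_LO else COIF1_HI
        arr <- dwt_axis_cpp(as.numeric(arr), as.integer(dim(arr)),
                            as.numeric(k), ax - 1L)
        arr <- array(arr, attr(arr, "dim"))
      }
      image_volume(arr, volume$spacing * 2)
    })
  }
  names(out) <- paste0("wavelet-", labels)
  out
}

#' Laplacian-of-Gaussian filter bank
#'
#' Band-pass (blob/edge) images at physical scales `sigmas` mm. Each response
#' is the scale-normalized Laplacian `sigma^2 * laplace(G_sigma * I)`: the
#' image is smoothed with a separable Gaussian (sigma expressed in voxels via
#' the spacing, truncated at 4 sigma, nearest-neighbour boundary), then the
#' discrete Laplacian is taken per axis. A constant image maps to exactly zero.
#'
#' @param volume an [image_volume()].
#' @param sigmas positive scales in mm; default `c(2, 4, 6)`.
#' @return Named list of `image_volume`s, names `log-sigma-<s>-mm`.
#' @export
log_bank <- function(volume, sigmas = c(2, 4, 6)) {
  stopifnot(inherits(volume, "image_volume"))
  if (any(sigmas <= 0)) stop("all sigma values must be > 0")
  out <- vector("list", length(sigmas))
  names(out) <- paste0("log-sigma-", sigmas, "-mm")
  d2 <- c(1, -2, 1)
  for (i in seq_along(sigmas)) {
    s <- sigmas[i]
    sm <- gaussian_smooth(volume$voxels, s, volume$spacing,
                          boundary = "nearest", truncate = 3)
    lap <- array(0, dim(sm))
    for (ax in 1:3) {
      ks <- list(NULL, NULL, NULL)
      ks[[ax]] <- d2 / volume$spacing[ax]^2
      lap <- lap + conv3d_sep(sm, ks, boundary = "nearest")
    }
    out[[i]] <- image_volume(s^2 * lap, volume$spacing)
  }
  out
}

#' Build the full derivative image set
#'
#' One original plus eleven derivative images: eight undecimated coiflet-1
#' wavelet sub-bands and three Laplacian-of-Gaussian responses. All twelve
#' share the input grid, so a single lesion mask indexes them all.
#'
#' @inheritParams log_bank
#' @return Named list of 12 `image_volume`s: `original`, `wavelet-*`, and
#'   `log-sigma-*-mm`, in that order.
#' @export
derivative_images <- function(volume, sigmas = c(2, 4, 6)) {
  c(list(original = volume), wavelet_bank(volume), log_bank(volume, sigmas))
}
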