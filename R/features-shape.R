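# boundary voxels: foreground with at least one 6-neighbour background/edge
boundary_voxels <- function(m) {
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nsum <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core == 1L & nsum < 6L, arr.ind = TRUE)
}

# anti-aliased iso-surface: Gaussian-smooth the padded binary field before the
# marching-tetrahedra pass, so the mesh tracks the digitized boundary instead
# of its voxel facets
mesh_quantities <- function(m, spacing, smooth_sigma_vox = 0.8) {
  d <- dim(m)
  pad <- 4L
  f <- array(0, d + 2L * pad)
  f[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <- m
  ks <- lapply(1:3, function(ax) gaussian_kernel(smooth_sigma_vox, truncate = 3))
  f <- conv3d_sep(f, ks, boundary = "nearest")
  av <- mesh_area_volume_cpp(as.numeric(f), as.integer(dim(f)),
                             as.numeric(spacing), 0.5)
  list(area = av[1], volume = av[2])
}

#' Shape features of a lesion mask
#'
#' The 14 standard 3D shape descriptors, computed from the (re-segmented)
#' mask geometry only; they are identical for every derivative image. Mesh
#' quantities (MeshVolume, SurfaceArea, SurfaceVolumeRatio, Sphericity) come
#' from a marching-tetrahedra triangulation of the 0.5 iso-level of the
#' lightly anti-aliased binary field (Gaussian, sigma 0.8 voxel), which
#' removes the voxel-facet area bias; a digitized ball therefore scores a
#' sphericity close to 1. Diameters are maximum pairwise distances between
#' boundary-voxel centres (overall, and within axial / coronal / sagittal
#' planes). Axis lengths are `4 * sqrt(eigenvalue)` of the voxel-coordinate
#' covariance; degenerate principal axes yield 0.
#'
#' @param mask a non-empty [lesion_mask()].
#' @param spacing optional spacing override (mm); defaults to the mask's.
#' @return named numeric vector of 14 features (lengths mm, areas mm^2,
#'   volumes mm^3).
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  m <- mask$voxels
  if (sum(m) == 0L) stop("mask is empty")
  sp <- if (is.null(spacing)) mask$spacing else spacing
  n <- sum(m)
  mq <- mesh_quantities(m, sp)
  # physical coordinates of foreground voxel centres
  idx <- which(m == 1L, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)
  bidx <- boundary_voxels(m)
  bpts <- sweep(bidx - 1, 2, sp, `*`)
  max3d <- if (nrow(bpts) > 1) max_pairwise_dist_cpp(bpts) else 0
  diam_plane <- function(group_col) {
    best <- 0
    for (g in unique(bidx[, group_col])) {
      sub <- bpts[bidx[, group_col] == g, , drop = FALSE]
      if (nrow(sub) > 1) best <- max(best, max_pairwise_dist_cpp(sub))
    }
    best
  }
  # PCA of voxel coordinates (population covariance)
  if (n > 1) {
    cov <- crossprod(sweep(pts, 2, colMeans(pts))) / n
    ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  c(Elongation = elong,
    Flatness = flat,
    LeastAxisLength = 4 * sqrt(ev[3]),
    MajorAxisLength = 4 * sqrt(ev[1]),
    Maximum2DDiameterColumn = diam_plane(2L), # within a coronal (x-z) plane
    Maximum2DDiameterRow = diam_plane(1L),    # within a sagittal (y-z) plane
    Maximum2DDiameterSlice = diam_plane(3L),  # within an axial (x-y) plane
    Maximum3DDiameter = max3d,
    MeshVolume = mq$volume,
    MinorAxisLength = 4 * sqrt(ev[2]),
    Sphericity = (36 * pi * mq$volume^2)^(1 / 3) / mq$area,
    SurfaceArea = mq$area,
    SurfaceVolumeRatio = mq$area / mq$volume,
    VoxelVolume = n * prod(sp))
}
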