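test_that("discretization follows the fixed-bin-width rule", {
  expect_equal(max(discretize(1:200, discretization_config(25))), 8)
  expect_equal(discretize(rep(5, 10)), rep(1L, 10))
  expect_equal(discretize(c(0, 10, 20, 30), discretization_config(10)),
               1:4)
  # bin-count mode: constant input collapses to level 1
  expect_equal(discretize(rep(3, 4), discretization_config(NULL, 4)),
               rep(1L, 4))
})

test_that("first-order features match direct formulas", {
  expect_equal(unname(first_order_features(c(1, 2, 3, 4))[c("Mean", "Range",
                                                            "RootMeanSquared")]),
               c(2.5, 3, sqrt(7.5)))
  f <- first_order_features(rep(7, 20))
  expect_equal(unname(f[c("Variance", "Uniformity", "Entropy", "Mean",
                          "Median", "Skewness", "Kurtosis")]),
               c(0, 1, 0, 7, 7, 0, 0))
  set.seed(99)
  x <- rnorm(10000)
  f2 <- first_order_features(x)
  expect_lt(abs(f2[["Skewness"]]), 0.1)
  expect_lt(abs(f2[["Kurtosis"]] - 3), 0.2) # non-excess convention
  # full cross-check against the definition oracle
  set.seed(5)
  y <- rnorm(500, 60, 12)
  got <- first_order_features(y, voxel_volume = 2)
  ref <- oracle_firstorder(y, W = 25, vv = 2)
  expect_equal(got[names(ref)], ref, tolerance = 1e-12)
})

test_that("shape features: single voxel and digitized ball", {
  m1 <- lesion_mask(array(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0,
                            0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                          c(3, 3, 3)))
  s1 <- shape_features(m1)
  expect_equal(s1[["VoxelVolume"]], 1)
  expect_equal(s1[["Maximum3DDiameter"]], 0)
  ball <- lesion_mask(make_ball(20))
  sb <- shape_features(ball)
  expect_gt(sb[["Sphericity"]], 0.97)
  expect_lte(sb[["Sphericity"]], 1.0)
  # sphericity approaches 1 from below as the ball grows
  sb10 <- shape_features(lesion_mask(make_ball(10)))
  expect_gt(sb[["Sphericity"]], sb10[["Sphericity"]])
  expect_lt(abs(sb[["Elongation"]] - 1), 0.02)
  expect_lt(abs(sb[["Flatness"]] - 1), 0.02)
  expect_equal(sb[["Maximum3DDiameter"]], 40)
  expect_lt(abs(sb[["VoxelVolume"]] - 4 / 3 * pi * 8000) / (4 / 3 * pi * 8000),
            0.05)
  expect_lt(abs(sb[["MeshVolume"]] - sb[["VoxelVolume"]]) / sb[["VoxelVolume"]],
            0.05)
})

test_that("analytic sphere mask volume at stated radius and spacing", {
  ball <- make_ball(10, spacing = c(1, 1, 1))
  vol <- sum(ball) # mm^3 on the 1 mm grid
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
})

test_that("GLCM matches hand enumeration on the 2x2 toy image", {
  # two columns of constant level along y: value pairs along x cross levels
  img <- image_volume(array(c(0, 0, 30, 30), c(2, 2, 1)))
  msk <- lesion_mask(array(1L, c(2, 2, 1)))
  tm <- texture_matrix(img, msk, "glcm")
  dirs <- hemorad:::DIRECTIONS_13
  i100 <- which(apply(dirs, 1, function(r) all(r == c(1, 0, 0))))
  # along x both neighbours stay in-level: counts {(1,1):2, (2,2):2}
  expect_equal(tm$matrix[, , i100], matrix(c(2, 0, 0, 2), 2))
  i010 <- which(apply(dirs, 1, function(r) all(r == c(0, 1, 0))))
  expect_equal(tm$matrix[, , i010], matrix(c(0, 2, 2, 0), 2))
  # normalized entries sum to 1 per direction with pairs
  for (k in seq_len(dim(tm$matrix)[3])) {
    s <- sum(tm$matrix[, , k])
    if (s > 0) expect_equal(sum(tm$matrix[, , k] / s), 1)
  }
})

test_that("degenerate texture conventions: diagonal and uniform GLCM, flat region", {
  P2 <- array(0, c(2, 2, 1)); P2[1, 1, 1] <- 0.5; P2[2, 2, 1] <- 0.5
  tfi <- texture_features(structure(list(kind = "glcm", matrix = P2,
                                         n_gray_levels = 2L, n_voxels = 4L),
                                    class = "texture_matrix"))
  expect_equal(tfi[["Contrast"]], 0)
  expect_equal(tfi[["MaximumProbability"]], 0.5)
  Pu <- array(0.25, c(2, 2, 1))
  tfu <- texture_features(structure(list(kind = "glcm", matrix = Pu,
                                         n_gray_levels = 2L, n_voxels = 4L),
                                    class = "texture_matrix"))
  expect_equal(tfu[["JointEntropy"]], 2) # 2 log2(2) bits
  im <- image_volume(array(50, c(3, 3, 3)))
  mk <- lesion_mask(array(1L, c(3, 3, 3)))
  tz <- texture_matrix(im, mk, "glszm")
  expect_equal(sum(tz$matrix), 1) # exactly one zone
  expect_equal(tz$matrix[1, 27], 1)
  tn <- texture_features(texture_matrix(im, mk, "ngtdm"))
  expect_equal(tn[["Coarseness"]], 1e6)
})

test_that("all five texture families match naive-loop oracles on random images", {
  for (seed in c(21, 22, 23)) {
    cs <- random_case(seed, n = 8)
    img <- image_volume(cs$img); msk <- lesion_mask(cs$msk)
    lev <- oracle_levels(cs$img, cs$msk)
    dirs <- hemorad:::DIRECTIONS_13
    # GLCM + GLRLM per direction
    tm <- texture_matrix(img, msk, "glcm")
    tr <- texture_matrix(img, msk, "glrlm")
    for (k in seq_len(nrow(dirs))) {
      expect_equal(tm$matrix[, , k], oracle_glcm_dir(lev, dirs[k, ]))
      ref_r <- oracle_glrlm_dir(lev, dirs[k, ])
      got_r <- tr$matrix[, seq_len(ncol(ref_r)), k]
      expect_equal(unname(got_r), unname(ref_r))
    }
    # GLSZM zones
    tz <- texture_matrix(img, msk, "glszm")
    ref_z <- oracle_glszm(lev)
    expect_equal(unname(tz$matrix[, seq_len(ncol(ref_z))]), unname(ref_z))
    # GLDM and NGTDM
    td <- texture_matrix(img, msk, "gldm")
    ref_d <- oracle_gldm(lev)
    expect_equal(unname(td$matrix),
                 unname(ref_d[, seq_len(ncol(td$matrix)), drop = FALSE]))
    tg <- texture_matrix(img, msk, "ngtdm")
    expect_equal(unname(tg$matrix), unname(oracle_ngtdm(lev)))
  }
})

test_that("texture feature values match definition oracles", {
  cs <- random_case(31, n = 8)
  img <- image_volume(cs$img); msk <- lesion_mask(cs$msk)
  lev <- oracle_levels(cs$img, cs$msk)
  np <- sum(cs$msk)
  dirs <- hemorad:::DIRECTIONS_13
  # GLCM: direction-averaged features
  got <- texture_features(texture_matrix(img, msk, "glcm"))
  ref <- rowMeans(vapply(seq_len(nrow(dirs)), function(k) {
    oracle_glcm_features(oracle_glcm_dir(lev, dirs[k, ]))
  }, numeric(24)))
  expect_equal(got, ref[names(got)], tolerance = 1e-10)
  # GLSZM
  gz <- texture_features(texture_matrix(img, msk, "glszm"))
  rz <- oracle_rlm_features(oracle_glszm(lev), np)
  expect_equal(unname(gz), unname(rz), tolerance = 1e-10)
  # NGTDM
  gn <- texture_features(texture_matrix(img, msk, "ngtdm"))
  rn <- oracle_ngtdm_features(oracle_ngtdm(lev), np)
  expect_equal(gn, rn[names(gn)], tolerance = 1e-10)
})

test_that("full extraction yields exactly 1,130 uniquely named finite features", {
  cs <- random_case(41, n = 10)
  v <- image_volume(cs$img); m <- lesion_mask(cs$msk)
  fv <- extract_features(v, m, extraction_config(crop_margin = 4))
  expect_length(fv, 1130)
  expect_false(any(duplicated(names(fv))))
  expect_true(all(is.finite(fv)))
  # census identities: 14 shape, 18 first-order x 12, 75 texture x 12
  cls <- sub("^.+_(shape|firstorder|glcm|glrlm|glszm|ngtdm|gldm)_.+$", "\\1",
             names(fv))
  expect_equal(sum(cls == "shape"), 14)
  expect_equal(sum(cls == "firstorder"), 18 * 12)
  expect_equal(sum(cls %in% c("glcm", "glrlm", "glszm", "ngtdm", "gldm")),
               75 * 12)
  # determinism
  fv2 <- extract_features(v, m, extraction_config(crop_margin = 4))
  expect_identical(fv, fv2)
})

test_that("direction-aggregated and shape features are invariant to 90-degree rotation", {
  cs <- random_case(51, n = 8)
  v <- image_volume(cs$img); m <- lesion_mask(cs$msk)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  vr <- image_volume(rot(cs$img)); mr <- lesion_mask(rot(cs$msk))
  cfg <- extraction_config(crop_margin = 4, sigmas = c(2, 4, 6))
  f1 <- extract_features(v, m, cfg)
  f2 <- extract_features(vr, mr, cfg)
  # texture families on the original image and shape features are
  # orientation-free; wavelet/LoG labels change roles under rotation
  keep <- grepl("^original_(glcm|glrlm|glszm|ngtdm|gldm|shape|firstorder)_",
                names(f1))
  mesh <- grepl("MeshVolume|SurfaceArea|Sphericity|SurfaceVolumeRatio",
                names(f1))
  keep <- keep & !grepl("Maximum2DDiameter", names(f1))
  expect_equal(f1[keep & !mesh], f2[keep & !mesh], tolerance = 1e-9)
  # mesh quantities: the tetrahedral decomposition is only approximately
  # rotation-symmetric
  expect_equal(f1[keep & mesh], f2[keep & mesh], tolerance = 1e-2)
})

test_that("adding a constant shifts Mean but not Variance or GLCM Contrast", {
  cs <- random_case(61, n = 8)
  v1 <- image_volume(cs$img); v2 <- image_volume(cs$img + 100)
  m <- lesion_mask(cs$msk)
  cfg <- extraction_config(crop_margin = 4)
  f1 <- extract_features(v1, m, cfg); f2 <- extract_features(v2, m, cfg)
  expect_equal(f2[["original_firstorder_Mean"]],
               f1[["original_firstorder_Mean"]] + 100, tolerance = 1e-9)
  expect_equal(f2[["original_firstorder_Variance"]],
               f1[["original_firstorder_Variance"]], tolerance = 1e-9)
  expect_equal(f2[["original_glcm_Contrast"]],
               f1[["original_glcm_Contrast"]], tolerance = 1e-9)
})

test_that("shape features are computed from the mask alone", {
  cs <- random_case(71, n = 8)
  m <- lesion_mask(cs$msk)
  cfg <- extraction_config(crop_margin = 4)
  f1 <- extract_features(image_volume(cs$img), m, cfg)
  f2 <- extract_features(image_volume(cs$img * 0.5 + 40), m, cfg)
  sh <- grep("_shape_", names(f1), value = TRUE)
  expect_equal(f1[sh], f2[sh])
})
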