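# the 13 unique 3D direction offsets (half of the 26-neighbourhood)
DIRECTIONS_13 <- {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# levels array: discretized masked image, 0 outside the region
levels_array <- function(image_arr, mask_arr, config) {
  vals <- image_arr[mask_arr == 1L]
  lev <- discretize(vals, config)
  out <- array(0L, dim(image_arr))
  out[mask_arr == 1L] <- lev
  list(levels = out, ng = max(lev))
}

#' Texture matrix construction
#'
#' Builds one of the five gray-level texture matrices from a discretized
#' masked image. Conventions: GLCM uses distance-1 neighbours over the 13
#' unique 3D directions and is symmetrized; GLRLM counts maximal
#' constant-level runs per direction; GLSZM zones are 26-connected; NGTDM and
#' GLDM use the full 26-neighbourhood, with GLDM dependence threshold
#' `alpha = 0` and dependence size counted as the number of dependent
#' neighbours plus one (the centre voxel).
#'
#' @param image an [image_volume()] (any intensity scale).
#' @param mask aligned [lesion_mask()] defining the region.
#' @param kind one of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @param config a [discretization_config()].
#' @param alpha GLDM dependence threshold (|level difference| <= alpha).
#' @return list with class `texture_matrix`: `kind`, `n_gray_levels`, and
#'   `matrix` (per-direction array for GLCM/GLRLM, a matrix otherwise), plus
#'   `n_voxels` in the region.
#' @export
texture_matrix <- function(image, mask, kind = c("glcm", "glrlm", "glszm",
                                                 "ngtdm", "gldm"),
                           config = discretization_config(), alpha = 0L) {
  kind <- match.arg(kind)
  check_aligned(image, mask)
  if (sum(mask$voxels) == 0L) stop("mask is empty")
  la <- levels_array(image$voxels, mask$voxels, config)
  lev <- as.integer(la$levels)
  d <- as.integer(dim(la$levels))
  ng <- la$ng
  np <- sum(mask$voxels)
  mat <- switch(kind,
    glcm = {
      raw <- glcm_cpp(lev, d, DIRECTIONS_13, ng)
      raw <- array(raw, c(ng, ng, nrow(DIRECTIONS_13)))
      for (k in seq_len(dim(raw)[3])) raw[, , k] <- raw[, , k] + t(raw[, , k])
      raw
    },
    glrlm = {
      maxrun <- max(d)
      raw <- glrlm_cpp(lev, d, DIRECTIONS_13, ng, maxrun)
      raw <- array(raw, c(ng, maxrun, nrow(DIRECTIONS_13)))
      used <- max(c(1L, which(apply(raw, 2, sum) > 0)))
      raw[, seq_len(used), , drop = FALSE]
    },
    glszm = {
      zones <- glszm_zones_cpp(lev, d)
      smax <- max(zones[, 2])
      m <- matrix(0, ng, smax)
      for (r in seq_len(nrow(zones))) {
        m[zones[r, 1], zones[r, 2]] <- m[zones[r, 1], zones[r, 2]] + 1
      }
      m
    },
    ngtdm = ngtdm_cpp(lev, d, ng),
    gldm = {
      m <- gldm_cpp(lev, d, as.integer(alpha))
      # dependence size = dependent neighbours + 1 (centre voxel)
      used <- max(which(colSums(m) > 0))
      m[, seq_len(used), drop = FALSE]
    })
  structure(list(kind = kind, matrix = mat, n_gray_levels = ng,
                 n_voxels = np), class = "texture_matrix")
}

# --- per-family feature definitions ---------------------------------------

glcm_features_one <- function(P) {
  s <- sum(P)
  if (s == 0) return(NULL)
  p <- P / s
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # p_{x+y} over k = 2..2Ng ; p_{x-y} over k = 0..Ng-1
  kxy <- 2:(2 * ng)
  pxy_sum <- vapply(kxy, function(k) sum(p[(i + j) == k]), numeric(1))
  kd <- 0:(ng - 1)
  pxy_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  hx <- -sum(plog2(px)); hy <- -sum(plog2(py))
  hxy <- -sum(plog2(p))
  pq <- outer(px, py)
  hxy1 <- -sum(ifelse(p > 0 & pq > 0, p * log2(pq), 0))
  hxy2 <- -sum(plog2(pq))
  da <- sum(kd * pxy_diff)
  corr <- if (sigx > 0 && sigy > 0) {
    (sum(i * j * p) - mux * muy) / (sigx * sigy)
  } else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  # MCC: second-largest eigenvalue of Q
  mcc <- if (ng == 1) 1 else {
    Q <- matrix(0, ng, ng)
    nzx <- px > 0; nzy <- py > 0
    for (k in which(nzy)) {
      Q <- Q + outer(p[, k], p[, k]) / py[k]
    }
    Q[nzx, ] <- Q[nzx, , drop = FALSE] / px[nzx]
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }
  offd <- abs(i - j) > 0
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(plog2(pxy_diff)),
    DifferenceVariance = sum((kd - da)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offd] / (i[offd] - j[offd])^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(kxy * pxy_sum),
    SumEntropy = -sum(plog2(pxy_sum)),
    SumSquares = sigx^2)
}

rlm_style_features <- function(P, np, prefix_short, prefix_long,
                               run_label, nu_label) {
  nr <- sum(P)
  p <- P / nr
  ng <- nrow(P); nl <- ncol(P)
  i <- row(P); j <- col(P)
  gl_sum <- rowSums(P); rl_sum <- colSums(P)
  mu_i <- sum(row(p) * p); mu_j <- sum(col(p) * p)
  out <- c(
    sum(P / j^2) / nr,                              # short emphasis
    sum(P * j^2) / nr,                              # long emphasis
    sum(gl_sum^2) / nr,                             # GLN
    sum(gl_sum^2) / nr^2,                           # GLNN
    sum(rl_sum^2) / nr,                             # RLN / SZN / DN
    sum(rl_sum^2) / nr^2,                           # RLNN / SZNN / DNN
    nr / np,                                        # percentage
    sum(p * (i - mu_i)^2),                          # gray level variance
    sum(p * (j - mu_j)^2),                          # run/zone variance
    -sum(plog2(p)),                                 # entropy
    sum(P / i^2) / nr,                              # low gray level
    sum(P * i^2) / nr,                              # high gray level
    sum(P / (i^2 * j^2)) / nr,
    sum(P * i^2 / j^2) / nr,
    sum(P * j^2 / i^2) / nr,
    sum(P * i^2 * j^2) / nr)
  names(out) <- c(paste0("Short", run_label, "Emphasis"),
                  paste0("Long", run_label, "Emphasis"),
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  paste0(nu_label, "NonUniformity"),
                  paste0(nu_label, "NonUniformityNormalized"),
                  paste0(run_label, "Percentage"),
                  "GrayLevelVariance", paste0(run_label, "Variance"),
                  paste0(run_label, "Entropy"),
                  paste0("LowGrayLevel", run_label, "Emphasis"),
                  paste0("HighGrayLevel", run_label, "Emphasis"),
                  paste0("Short", run_label, "LowGrayLevelEmphasis"),
                  paste0("Short", run_label, "HighGrayLevelEmphasis"),
                  paste0("Long", run_label, "LowGrayLevelEmphasis"),
                  paste0("Long", run_label, "HighGrayLevelEmphasis"))
  out
}

glszm_features <- function(P, np) {
  v <- rlm_style_features(P, np, run_label = "Zone", nu_label = "SizeZone")
  names(v) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                "LargeAreaHighGrayLevelEmphasis")
  v
}

gldm_features <- function(P, np) {
  v <- rlm_style_features(P, np, run_label = "Dependence", nu_label = "Dependence")
  # GLDM has no normalized gray-level non-uniformity and no percentage
  keep <- c("ShortDependenceEmphasis", "LongDependenceEmphasis",
            "GrayLevelNonUniformity", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy",
            "LowGrayLevelDependenceEmphasis", "HighGrayLevelDependenceEmphasis",
            "ShortDependenceLowGrayLevelEmphasis",
            "ShortDependenceHighGrayLevelEmphasis",
            "LongDependenceLowGrayLevelEmphasis",
            "LongDependenceHighGrayLevelEmphasis")
  names(v) <- c("ShortDependenceEmphasis", "LongDependenceEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "DependenceNonUniformity", "DependenceNonUniformityNormalized",
                "DependencePercentage", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelDependenceEmphasis", "HighGrayLevelDependenceEmphasis",
                "ShortDependenceLowGrayLevelEmphasis",
                "ShortDependenceHighGrayLevelEmphasis",
                "LongDependenceLowGrayLevelEmphasis",
                "LongDependenceHighGrayLevelEmphasis")
  v <- v[keep]
  names(v) <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")
  v
}

ngtdm_features <- function(M, np) {
  ni <- M[, 1]; si <- M[, 2]
  nvp <- sum(ni)
  p <- ni / nvp
  lv <- seq_len(nrow(M))
  nz <- p > 0
  ngp <- sum(nz)
  coars_den <- sum(p * si)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[nz], p[nz]) * outer(lv[nz], lv[nz], `-`)^2) /
       (ngp * (ngp - 1))) * (sum(si) / nvp)
  } else 0
  busy_den <- sum(abs(outer(lv[nz] * p[nz], lv[nz] * p[nz], `-`)))
  busyness <- if (busy_den > 0) sum(p * si) / busy_den else 0
  # complexity and strength: double sums over pairs with p_i, p_j > 0
  iL <- lv[nz]; pL <- p[nz]; sL <- si[nz]
  pi_m <- outer(pL, pL, `+`)
  dif <- abs(outer(iL, iL, `-`))
  complexity <- sum(dif * (outer(pL * sL, rep(1, ngp)) +
                             outer(rep(1, ngp), pL * sL)) / pi_m) / nvp
  strength <- if (sum(si) > 0) sum(pi_m * dif^2) / sum(si) else 0
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

# vectorized-across-directions GLCM features; Parr = ng x ng x nd counts
glcm_features_dirs <- function(Parr) {
  ng <- dim(Parr)[1]; nd <- dim(Parr)[3]
  M <- matrix(Parr, ng * ng, nd)
  tot <- colSums(M)
  use <- tot > 0
  if (!any(use)) return(glcm_features_one(matrix(1, 1, 1)))
  M <- M[, use, drop = FALSE]
  nd <- ncol(M)
  p <- sweep(M, 2, colSums(M), `/`)
  iv <- rep(seq_len(ng), times = ng)
  jv <- rep(seq_len(ng), each = ng)
  lev <- seq_len(ng)
  px <- rowsum(p, iv); py <- rowsum(p, jv)           # ng x nd
  LV <- matrix(lev, ng, nd)
  mux <- colSums(px * LV); muy <- colSums(py * LV)
  sigx2 <- colSums(px * (LV - rep(mux, each = ng))^2)
  sigy2 <- colSums(py * (LV - rep(muy, each = ng))^2)
  psum <- rowsum(p, iv + jv)                          # (2ng-1) x nd
  kxy <- as.numeric(rownames(psum))
  pdiff <- rowsum(p, abs(iv - jv))                    # ng x nd
  kd <- as.numeric(rownames(pdiff))
  hx <- -colSums(plog2(px)); hy <- -colSums(plog2(py))
  hxy <- -colSums(plog2(p))
  PXPY <- px[iv, , drop = FALSE] * py[jv, , drop = FALSE]
  lq <- log2(pmax(PXPY, 1e-300))
  hxy1 <- -colSums(p * lq * (p > 0))
  hxy2 <- -colSums(plog2(PXPY))
  da <- colSums(pdiff * kd)
  KD <- matrix(kd, length(kd), nd)
  dv <- colSums((KD - rep(da, each = length(kd)))^2 * pdiff)
  sig <- sqrt(sigx2 * sigy2)
  corr <- ifelse(sig > 0, (colSums(iv * jv * p) - mux * muy) / sig, 1)
  hmax <- pmax(hx, hy)
  imc1 <- ifelse(hmax > 0, (hxy - hxy1) / hmax, 0)
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offd <- iv != jv
  invvar <- colSums(p[offd, , drop = FALSE] / (iv[offd] - jv[offd])^2)
  csum <- iv + jv
  # MCC: sqrt of the second-largest eigenvalue of Q(i,j) = sum_k p_ik p_jk /
  # (px_i py_k). Q is similar to the symmetric Dx^{-1/2} P Dy^{-1} P' Dx^{-1/2}
  # on the support of px, so a symmetric eigensolver applies.
  mcc <- vapply(seq_len(nd), function(d) {
    if (ng == 1) return(1)
    pd <- matrix(p[, d], ng, ng)
    nzx <- px[, d] > 0; nzy <- py[, d] > 0
    if (sum(nzx) < 2) return(1)
    Pn <- pd[nzx, nzy, drop = FALSE]
    A <- Pn %*% (t(Pn) / py[nzy, d])
    isq <- 1 / sqrt(px[nzx, d])
    B <- A * tcrossprod(isq)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(ev[2], 0))
  }, numeric(1))
  feats <- rbind(
    Autocorrelation = colSums(iv * jv * p),
    ClusterProminence = colSums((csum - rep(mux + muy, each = ng * ng))^4 * p),
    ClusterShade = colSums((csum - rep(mux + muy, each = ng * ng))^3 * p),
    ClusterTendency = colSums((csum - rep(mux + muy, each = ng * ng))^2 * p),
    Contrast = colSums((iv - jv)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -colSums(plog2(pdiff)),
    DifferenceVariance = dv,
    Id = colSums(p / (1 + abs(iv - jv))),
    Idm = colSums(p / (1 + (iv - jv)^2)),
    Idmn = colSums(p / (1 + (iv - jv)^2 / ng^2)),
    Idn = colSums(p / (1 + abs(iv - jv) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = invvar,
    JointAverage = mux,
    JointEnergy = colSums(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = apply(p, 2, max),
    SumAverage = colSums(psum * kxy),
    SumEntropy = -colSums(plog2(psum)),
    SumSquares = sigx2)
  rowMeans(feats)
}

# vectorized-across-directions GLRLM features; Parr = ng x nl x nd counts
glrlm_features_dirs <- function(Parr, np) {
  ng <- dim(Parr)[1]; nl <- dim(Parr)[2]; nd <- dim(Parr)[3]
  M <- matrix(Parr, ng * nl, nd)
  iv <- rep(seq_len(ng), times = nl)
  jv <- rep(seq_len(nl), each = ng)
  nr <- colSums(M)
  p <- sweep(M, 2, nr, `/`)
  g <- rowsum(M, iv); rl <- rowsum(M, jv)
  mu_i <- colSums(p * iv); mu_j <- colSums(p * jv)
  feats <- rbind(
    ShortRunEmphasis = colSums(M / jv^2) / nr,
    LongRunEmphasis = colSums(M * jv^2) / nr,
    GrayLevelNonUniformity = colSums(g^2) / nr,
    GrayLevelNonUniformityNormalized = colSums(g^2) / nr^2,
    RunLengthNonUniformity = colSums(rl^2) / nr,
    RunLengthNonUniformityNormalized = colSums(rl^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = colSums(p * (iv - rep(mu_i, each = ng * nl))^2),
    RunVariance = colSums(p * (jv - rep(mu_j, each = ng * nl))^2),
    RunEntropy = -colSums(plog2(p)),
    LowGrayLevelRunEmphasis = colSums(M / iv^2) / nr,
    HighGrayLevelRunEmphasis = colSums(M * iv^2) / nr,
    ShortRunLowGrayLevelEmphasis = colSums(M / (iv^2 * jv^2)) / nr,
    ShortRunHighGrayLevelEmphasis = colSums(M * iv^2 / jv^2) / nr,
    LongRunLowGrayLevelEmphasis = colSums(M * jv^2 / iv^2) / nr,
    LongRunHighGrayLevelEmphasis = colSums(M * iv^2 * jv^2) / nr)
  rowMeans(feats)
}

#' Texture features from a texture matrix
#'
#' Computes the standard named features of the matrix's family: 24 GLCM, 16
#' GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM features (75 in total across the five
#' families). GLCM and GLRLM features are computed per direction and averaged
#' over the 13 directions. Undefined expressions on degenerate regions
#' (single gray level, single voxel) follow fixed conventions: Correlation and
#' MCC of a one-level region are 1, information measures and variances are 0,
#' and NGTDM Coarseness of a flat region is capped at 1e6.
#'
#' @param tm a [texture_matrix()].
#' @return named numeric vector (24, 16, 16, 5 or 14 features).
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"))
  np <- tm$n_voxels
  switch(tm$kind,
    glcm = glcm_features_dirs(tm$matrix),
    glrlm = glrlm_features_dirs(tm$matrix, np),
    glszm = glszm_features(tm$matrix, np),
    gldm = gldm_features(tm$matrix, np),
    ngtdm = ngtdm_features(tm$matrix, np))
}
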