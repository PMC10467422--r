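# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: plain loops and direct textbook formulas only.

# digitized ball mask on an isotropic grid
make_ball <- function(radius, spacing = c(1, 1, 1), pad = 4) {
  d <- 2 * ceiling(radius / spacing) + 2 * pad + 1
  ctr <- (d - 1) / 2 * spacing
  arr <- array(0L, d)
  for (k in seq_len(d[3])) {
    z2 <- ((k - 1) * spacing[3] - ctr[3])^2
    for (j in seq_len(d[2])) {
      y2 <- ((j - 1) * spacing[2] - ctr[2])^2
      x2 <- ((seq_len(d[1]) - 1) * spacing[1] - ctr[1])^2
      arr[, j, k] <- as.integer(x2 + y2 + z2 <= radius^2)
    }
  }
  arr
}

# random test image + blob mask on a small grid
random_case <- function(seed, n = 10, levels = 6) {
  set.seed(seed)
  d <- rep(n, 3)
  img <- array(sample.int(levels, prod(d), replace = TRUE) * 10 + 25, d)
  msk <- make_ball(n / 2 - 1.2, pad = 1)[1:d[1], 1:d[2], 1:d[3]]
  # roughen the mask a little
  flip <- which(msk == 1L)
  msk[sample(flip, max(1, length(flip) %/% 10))] <- 0L
  if (sum(msk) < 8) msk[1:2, 1:2, 1:2] <- 1L
  list(img = img, msk = msk)
}

# --- texture matrix oracles (naive loops) ---------------------------------

all_26_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

oracle_glcm_dir <- function(lev, off) {
  d <- dim(lev)
  ng <- max(lev)
  P <- matrix(0, ng, ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l1 <- lev[x, y, z]
    if (l1 <= 0) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    l2 <- lev[x2, y2, z2]
    if (l2 <= 0) next
    P[l1, l2] <- P[l1, l2] + 1
  }
  P + t(P) # symmetrized
}

oracle_glrlm_dir <- function(lev, off) {
  d <- dim(lev)
  ng <- max(lev)
  runs <- integer(0); glev <- integer(0)
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- lev[x, y, z]
    if (l <= 0) next
    prev <- c(x, y, z) - off
    if (inb(prev) && lev[prev[1], prev[2], prev[3]] == l) next
    len <- 1
    nxt <- c(x, y, z) + off
    while (inb(nxt) && lev[nxt[1], nxt[2], nxt[3]] == l) {
      len <- len + 1
      nxt <- nxt + off
    }
    runs <- c(runs, len); glev <- c(glev, l)
  }
  P <- matrix(0, ng, max(runs))
  for (i in seq_along(runs)) P[glev[i], runs[i]] <- P[glev[i], runs[i]] + 1
  P
}

oracle_glszm <- function(lev) {
  d <- dim(lev)
  ng <- max(lev)
  seen <- array(FALSE, d)
  offs <- all_26_offsets()
  zones <- list()
  idx_all <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    p0 <- idx_all[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    l <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0); seen[p0[1], p0[2], p0[3]] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == l) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones[[length(zones) + 1]] <- c(l, size)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zm[, 2]))
  for (i in seq_len(nrow(zm))) P[zm[i, 1], zm[i, 2]] <- P[zm[i, 1], zm[i, 2]] + 1
  P
}

oracle_gldm <- function(lev, alpha = 0) {
  d <- dim(lev)
  ng <- max(lev)
  offs <- all_26_offsets()
  P <- matrix(0, ng, 27)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- lev[x, y, z]
    if (l <= 0) next
    dep <- 0
    for (o in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      l2 <- lev[q[1], q[2], q[3]]
      if (l2 > 0 && abs(l2 - l) <= alpha) dep <- dep + 1
    }
    P[l, dep + 1] <- P[l, dep + 1] + 1
  }
  P
}

oracle_ngtdm <- function(lev) {
  d <- dim(lev)
  ng <- max(lev)
  offs <- all_26_offsets()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    l <- lev[x, y, z]
    if (l <= 0) next
    vals <- c()
    for (o in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      l2 <- lev[q[1], q[2], q[3]]
      if (l2 > 0) vals <- c(vals, l2)
    }
    n_i[l] <- n_i[l] + 1
    if (length(vals)) s_i[l] <- s_i[l] + abs(l - mean(vals))
  }
  cbind(n_i, s_i)
}

# --- per-family feature oracles (direct definitions, explicit loops) ------

olog2 <- function(x) if (x > 0) log2(x) else 0

oracle_glcm_features <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Correlation = 0,
         DifferenceAverage = 0, DifferenceEntropy = 0, DifferenceVariance = 0,
         Id = 0, Idm = 0, Idmn = 0, Idn = 0, Imc1 = 0, Imc2 = 0,
         InverseVariance = 0, JointAverage = mux, JointEnergy = 0,
         JointEntropy = 0, MCC = 0, MaximumProbability = max(p),
         SumAverage = 0, SumEntropy = 0, SumSquares = sx^2)
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * v
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - mux - muy)^4 * v
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - mux - muy)^3 * v
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - mux - muy)^2 * v
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * v
    f["Id"] <- f["Id"] + v / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + v / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + v / (1 + (i - j)^2 / ng^2)
    f["Idn"] <- f["Idn"] + v / (1 + abs(i - j) / ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + v / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + v^2
    hxy <- hxy - v * olog2(v)
    hxy1 <- hxy1 - (if (v > 0) v * olog2(px[i] * py[j]) else 0)
    hxy2 <- hxy2 - px[i] * py[j] * olog2(px[i] * py[j])
    psum[i + j] <- psum[i + j] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
  }
  f["JointEntropy"] <- hxy
  da <- sum((0:(ng - 1)) * pdif)
  f["DifferenceAverage"] <- da
  f["DifferenceEntropy"] <- -sum(sapply(pdif, function(q) q * olog2(q)))
  f["DifferenceVariance"] <- sum((0:(ng - 1) - da)^2 * pdif)
  f["SumAverage"] <- sum(seq_along(psum) * psum)
  f["SumEntropy"] <- -sum(sapply(psum, function(q) q * olog2(q)))
  f["Correlation"] <- if (sx > 0 && sy > 0) {
    (f[["Autocorrelation"]] - mux * muy) / (sx * sy)
  } else 1
  hx <- -sum(sapply(px, function(q) q * olog2(q)))
  hy <- -sum(sapply(py, function(q) q * olog2(q)))
  f["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  f["Imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  # MCC via the full (non-symmetric) Q matrix definition
  if (ng == 1) {
    f["MCC"] <- 1
  } else {
    Q <- matrix(0, ng, ng)
    for (i in 1:ng) for (j in 1:ng) {
      s <- 0
      for (k in 1:ng) {
        if (px[i] > 0 && py[k] > 0) s <- s + p[i, k] * p[j, k] / (px[i] * py[k])
      }
      Q[i, j] <- s
    }
    keep <- px > 0
    ev <- sort(Re(eigen(Q[keep, keep, drop = FALSE],
                        only.values = TRUE)$values), decreasing = TRUE)
    f["MCC"] <- if (length(ev) < 2) 1 else sqrt(max(ev[2], 0))
  }
  f
}

oracle_rlm_features <- function(P, np, short, long, gl_names) {
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  p <- P / nr
  out <- numeric(0)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0
  lrh <- 0; ent <- 0; mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    v <- P[i, j]
    sre <- sre + v / j^2; lre <- lre + v * j^2
    lgl <- lgl + v / i^2; hgl <- hgl + v * i^2
    srl <- srl + v / (i^2 * j^2); srh <- srh + v * i^2 / j^2
    lrl <- lrl + v * j^2 / i^2; lrh <- lrh + v * i^2 * j^2
    ent <- ent - p[i, j] * olog2(p[i, j])
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  glv <- 0; rv <- 0
  for (i in 1:ng) for (j in 1:nl) {
    glv <- glv + p[i, j] * (i - mu_i)^2
    rv <- rv + p[i, j] * (j - mu_j)^2
  }
  c(sre / nr, lre / nr, sum(rowSums(P)^2) / nr, sum(rowSums(P)^2) / nr^2,
    sum(colSums(P)^2) / nr, sum(colSums(P)^2) / nr^2, nr / np, glv, rv, ent,
    lgl / nr, hgl / nr, srl / nr, srh / nr, lrl / nr, lrh / nr)
}

oracle_ngtdm_features <- function(M, np) {
  ni <- M[, 1]; si <- M[, 2]
  nvp <- sum(ni); p <- ni / nvp
  lv <- seq_len(nrow(M)); nz <- which(p > 0); ngp <- length(nz)
  coars <- if (sum(p * si) > 0) 1 / sum(p * si) else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in nz) for (j in nz) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * si[i] + p[j] * si[j]) /
      (p[i] + p[j])
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(si) / nvp else 0
  busy <- if (busy_den > 0) sum(p * si) / busy_den else 0
  strength <- if (sum(si) > 0) strength / sum(si) else 0
  c(Busyness = unname(busy), Coarseness = unname(coars),
    Complexity = unname(complexity) / nvp, Contrast = unname(contrast),
    Strength = unname(strength))
}

# first-order features from definitions
oracle_firstorder <- function(x, W = 25, vv = 1) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lev <- floor((x - min(x)) / W) + 1
  p <- as.numeric(table(lev)) / n
  q <- quantile(x, c(.1, .25, .75, .9), type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  c(Energy = sum(x^2), Entropy = -sum(p * log2(p)),
    InterquartileRange = unname(q[3] - q[2]),
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(x), Mean = mu, MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    Median = median(x), Minimum = min(x),
    `10Percentile` = unname(q[1]), `90Percentile` = unname(q[4]),
    Range = diff(range(x)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = vv * sum(x^2), Uniformity = sum(p^2), Variance = m2)
}

# AUC by exhaustive pair counting (ties = 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# direct dense 3D convolution (cross-correlation) with symmetric boundary
oracle_conv3d <- function(arr, kernels, origins) {
  d <- dim(arr)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- array(0, d)
  k1 <- kernels[[1]]; k2 <- kernels[[2]]; k3 <- kernels[[3]]
  o1 <- origins[[1]]; o2 <- origins[[2]]; o3 <- origins[[3]]
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    s <- 0
    for (a in seq_along(k1)) for (b in seq_along(k2)) for (cc in seq_along(k3)) {
      xi <- refl(x - (o1 + 1) + a, d[1])
      yi <- refl(y - (o2 + 1) + b, d[2])
      zi <- refl(z - (o3 + 1) + cc, d[3])
      s <- s + k1[a] * k2[b] * k3[cc] * arr[xi, yi, zi]
    }
    out[x, y, z] <- s
  }
  out
}

# package-convention discretization for oracle use
oracle_levels <- function(img, msk, W = 25) {
  vals <- img[msk == 1]
  lev <- array(0L, dim(img))
  lev[msk == 1] <- as.integer(floor((vals - min(vals)) / W) + 1)
  lev
}

# rank-based Mann-Whitney AUC (fast, for large-n property tests)
oracle_auc_fast <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# latent-property draws straight from the spec marginals (test plumbing,
# bypasses image rendering; volume is the analytic target volume)
draw_latents_for_test <- function(spec, n) {
  v <- exp(rnorm(n, spec$volume_meanlog, spec$volume_sdlog))
  v <- pmin(pmax(v, spec$volume_range_cm3[1]), spec$volume_range_cm3[2])
  data.frame(
    volume_cm3 = v, log_volume = log(v),
    mean_hu = rnorm(n, spec$mean_hu_mean, spec$mean_hu_sd),
    heterogeneity = exp(rnorm(n, spec$het_meanlog, spec$het_sdlog)),
    irregularity = rbeta(n, spec$irregularity_shape1, spec$irregularity_shape2),
    slice_thickness = sample(spec$slice_thickness_levels, n, replace = TRUE,
                             prob = spec$slice_thickness_weights))
}

oracle_glrlm_features <- function(P, np) {
  stats::setNames(oracle_rlm_features(P, np),
                  c("ShortRunEmphasis", "LongRunEmphasis",
                    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                    "RunPercentage", "GrayLevelVariance", "RunVariance",
                    "RunEntropy", "LowGrayLevelRunEmphasis",
                    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                    "ShortRunHighGrayLevelEmphasis",
                    "LongRunLowGrayLevelEmphasis",
                    "LongRunHighGrayLevelEmphasis"))
}

oracle_glszm_features <- function(P, np) {
  stats::setNames(oracle_rlm_features(P, np),
                  c("SmallAreaEmphasis", "LargeAreaEmphasis",
                    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                    "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                    "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                    "SmallAreaHighGrayLevelEmphasis",
                    "LargeAreaLowGrayLevelEmphasis",
                    "LargeAreaHighGrayLevelEmphasis"))
}

oracle_gldm_features <- function(P, np) {
  v <- oracle_rlm_features(P, np)
  # the GLDM family replaces the normalized gray-level non-uniformity and the
  # percentage with nothing (14 features); map by position
  stats::setNames(v[c(1, 2, 3, 5, 6, 8, 9, 10, 11, 12, 13, 14, 15, 16)],
                  c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                    "GrayLevelNonUniformity", "DependenceNonUniformity",
                    "DependenceNonUniformityNormalized", "GrayLevelVariance",
                    "DependenceVariance", "DependenceEntropy",
                    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                    "SmallDependenceLowGrayLevelEmphasis",
                    "SmallDependenceHighGrayLevelEmphasis",
                    "LargeDependenceLowGrayLevelEmphasis",
                    "LargeDependenceHighGrayLevelEmphasis"))
}
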