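#' Synthetic cohort specification
#'
#' Describes an ATACH-2-like population of patients with acute spontaneous
#' supratentorial intracerebral hemorrhage: cohort size, hematoma-expansion
#' (HE) prevalence, the latent lesion properties that carry the planted HE
#' effect, acquisition geometry (in-plane spacing, slice-thickness levels),
#' and the clinical marginals to emulate. The planted effect acts on
#' standardized latent lesion properties through a logistic model whose scale
#' is calibrated at generation time so the population AUC of the true
#' log-odds score equals `auc_target`.
#'
#' Default clinical marginals reproduce the discovery-cohort summary of the
#' emulated trial population: glucose 140.4 (59.8) mg/dL, platelets 223.0
#' (62.3) 10^3/mm^3, onset-to-CT 98.1 (49.6) min, male fraction 0.592,
#' binned NIHSS/GCS frequencies, visual-marker prevalences (e.g. hypodensity
#' 75.5%), baseline hematoma volume 12.6 (12.7) cm^3 capped at 60 cm^3, and
#' ~2.9% missing 90-day mRS.
#'
#' @param n_patients cohort size (>= 2).
#' @param he_prevalence HE fraction, strictly inside (0, 1).
#' @param auc_target planned discriminability of the true latent score, in
#'   `[0.5, 1)`.
#' @param planted_feature_effects named log-odds coefficients on the
#'   standardized latent properties `log_volume`, `mean_hu`, `heterogeneity`,
#'   `irregularity` (relative weights; overall scale is calibrated).
#' @param marker_signal strength of the visual-marker link to the latent
#'   irregularity/heterogeneity (0 = markers are pure marginal noise).
#' @param slice_thickness_levels,slice_thickness_weights discrete scanner
#'   slice-thickness levels (mm) and sampling weights.
#' @param in_plane_spacing axial pixel spacing in mm.
#' @param volume_mean_cm3,volume_sd_cm3 mean/SD of baseline lesion volume
#'   (lognormal, truncated to `volume_range_cm3`).
#' @param volume_range_cm3 admissible baseline volumes (trial cap 60 cm^3).
#' @param mean_hu_mean,mean_hu_sd lesion mean density marginal (HU).
#' @param het_meanlog,het_sdlog lognormal parameters of the interior
#'   heterogeneity (HU SD of the textured interior).
#' @param irregularity_shape1,irregularity_shape2 Beta parameters of the
#'   boundary-irregularity dial in the unit interval.
#' @param texture_corr_mm correlation length of the interior texture field.
#' @param clinical_marginals list of per-variable marginals (see defaults).
#' @param mrs_missing fraction of missing 90-day mRS.
#' @param grid_dims optional fixed grid (voxels); default sizes the grid
#'   adaptively to the lesion plus `grid_margin_vox` margin.
#' @param grid_margin_vox margin (voxels) around the lesion extent.
#' @return list with class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 897L,
                        he_prevalence = 0.27,
                        auc_target = 0.65,
                        planted_feature_effects = c(log_volume = 0.9,
                                                    mean_hu = -0.7,
                                                    heterogeneity = 0.5,
                                                    irregularity = 0.2),
                        marker_signal = 1,
                        slice_thickness_levels = c(2.5, 5, 7.5),
                        slice_thickness_weights = c(0.2, 0.5, 0.3),
                        in_plane_spacing = 0.46,
                        volume_mean_cm3 = 12.6,
                        volume_sd_cm3 = 12.7,
                        volume_range_cm3 = c(0.5, 60),
                        mean_hu_mean = 60,
                        mean_hu_sd = 8,
                        het_meanlog = log(8),
                        het_sdlog = 0.4,
                        irregularity_shape1 = 2,
                        irregularity_shape2 = 6,
                        texture_corr_mm = 2,
                        clinical_marginals = default_clinical_marginals(),
                        mrs_missing = 0.029,
                        grid_dims = NULL,
                        grid_margin_vox = 10L) {
  if (n_patients < 2) stop("`n_patients` must be >= 2")
  if (he_prevalence <= 0 || he_prevalence >= 1) {
    stop("`he_prevalence` must be strictly inside (0, 1)")
  }
  if (auc_target < 0.5 || auc_target >= 1) {
    stop("`auc_target` must be in [0.5, 1)")
  }
  sds <- c(volume_sd_cm3, mean_hu_sd,
           unlist(lapply(clinical_marginals[c("glucose", "platelets",
                                              "onset_to_ct")], `[[`, "sd")))
  if (any(sds <= 0)) stop("all marginal SDs must be > 0")
  if (length(slice_thickness_levels) != length(slice_thickness_weights)) {
    stop("slice thickness levels and weights differ in length")
  }
  # lognormal parameters matching the target mean/SD, before truncation
  cv2 <- (volume_sd_cm3 / volume_mean_cm3)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(volume_mean_cm3) - sdlog^2 / 2
  structure(list(
    n_patients = as.integer(n_patients), he_prevalence = he_prevalence,
    auc_target = auc_target, planted_feature_effects = planted_feature_effects,
    marker_signal = marker_signal,
    slice_thickness_levels = slice_thickness_levels,
    slice_thickness_weights = slice_thickness_weights /
      sum(slice_thickness_weights),
    in_plane_spacing = in_plane_spacing,
    volume_meanlog = meanlog, volume_sdlog = sdlog,
    volume_range_cm3 = volume_range_cm3,
    mean_hu_mean = mean_hu_mean, mean_hu_sd = mean_hu_sd,
    het_meanlog = het_meanlog, het_sdlog = het_sdlog,
    irregularity_shape1 = irregularity_shape1,
    irregularity_shape2 = irregularity_shape2,
    texture_corr_mm = texture_corr_mm,
    clinical_marginals = clinical_marginals,
    mrs_missing = mrs_missing,
    grid_dims = grid_dims, grid_margin_vox = as.integer(grid_margin_vox)
  ), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @details `default_clinical_marginals()` returns the discovery-cohort
#'   marginals used by the defaults; override entries to change them.
#' @export
default_clinical_marginals <- function() {
  list(
    glucose = list(mean = 140.4, sd = 59.8),
    platelets = list(mean = 223.0, sd = 62.3),
    onset_to_ct = list(mean = 98.1, sd = 49.6),
    male_frac = 0.592,
    nihss_bins = list(breaks = c(0, 5, 10, 15, 20, 26, 43),
                      probs = c(0.165, 0.290, 0.249, 0.165, 0.087, 0.038)),
    gcs_bins = list(breaks = c(3, 9, 12, 15, 16),
                    probs = c(0.027, 0.125, 0.281, 0.567)),
    marker_probs = c(blend = 0.087, hypodensity = 0.755, swirl = 0.069,
                     black_hole = 0.087, fluid_level = 0.002, island = 0.040,
                     satellite = 0.145, irregular_shape = 0.290),
    mrs_probs = c(0.13, 0.15, 0.16, 0.17, 0.16, 0.14, 0.06)
  )
}

#' @rdname cohort_spec
#' @param ... overrides passed to `cohort_spec()`.
#' @details `compact_cohort_spec()` is a reduced-size preset (smaller lesions
#'   on a coarser-margin grid with thin-slice levels and 1 mm-scale in-plane
#'   spacing) that keeps a two-cohort study extractable in minutes; all
#'   planted-effect machinery is identical to the full-size spec.
#' @export
compact_cohort_spec <- function(n_patients = 900L, ...) {
  cohort_spec(n_patients = n_patients,
              in_plane_spacing = 0.9,
              slice_thickness_levels = c(1.5, 2.5, 3.5),
              slice_thickness_weights = c(0.3, 0.5, 0.2),
              volume_mean_cm3 = 1.7, volume_sd_cm3 = 1.3,
              volume_range_cm3 = c(0.35, 8),
              grid_margin_vox = 6L,
              ...)
}

# deterministic per-patient / per-stream sub-seed (< 2^31)
patient_seed <- function(seed, patient_index, stream = 1L) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(patient_index) * 7919 +
                as.numeric(stream) * 104729) %% 2147483629) + 1L
}

# unit-variance Gaussian random field: smoothed white noise, theoretical
# normalization via the kernel energy
grf_unit <- function(dims, sigma_mm, spacing) {
  noise <- array(rnorm(prod(dims)), dims)
  ks <- lapply(1:3, function(ax) gaussian_kernel(sigma_mm / spacing[ax], 3))
  sm <- conv3d_sep(noise, ks, boundary = "symmetric")
  norm <- sqrt(prod(vapply(ks, function(k) sum(k^2), numeric(1))))
  sm / norm
}

#' Generate one synthetic ICH lesion
#'
#' Draws the patient's latent lesion properties (volume, mean density,
#' interior heterogeneity, boundary irregularity, slice thickness) and
#' renders an anisotropic-voxel head-CT-like volume: a smoothed
#' random-ellipsoid lesion whose radius is modulated by a random-bump
#' directional field (irregularity dial), filled with a spatially correlated
#' Gaussian density field of SD `heterogeneity` HU around `mean_hu`
#' (heterogeneity 0 gives an exactly constant interior), over a textured
#' background of roughly 0--40 HU. Pure function of `(spec, patient_index,
#' seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index 1-based patient number.
#' @param seed integer run seed.
#' @return list: `volume` ([image_volume()]), `mask` ([lesion_mask()]),
#'   `latents` (named list incl. measured `volume_cm3` and `log_volume`).
#' @export
generate_lesion <- function(spec, patient_index, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(patient_seed(seed, patient_index, 1L))
  # latent draws
  v_target <- exp(rnorm(1, spec$volume_meanlog, spec$volume_sdlog))
  v_target <- min(max(v_target, spec$volume_range_cm3[1]),
                  spec$volume_range_cm3[2])
  mean_hu <- rnorm(1, spec$mean_hu_mean, spec$mean_hu_sd)
  het <- exp(rnorm(1, spec$het_meanlog, spec$het_sdlog))
  irr <- rbeta(1, spec$irregularity_shape1, spec$irregularity_shape2)
  thick <- sample(spec$slice_thickness_levels, 1L,
                  prob = spec$slice_thickness_weights)
  spacing <- c(spec$in_plane_spacing, spec$in_plane_spacing, thick)
  # ellipsoid semi-axes (mm), volume preserved under anisotropy
  r <- (3 * v_target * 1000 / (4 * pi))^(1 / 3)
  e <- exp(rnorm(3, 0, 0.12))
  e <- e / prod(e)^(1 / 3)
  axes <- r * e
  # grid sized to lesion + margin (or fixed by the spec)
  ext <- axes * (1 + 1.8 * irr)
  need <- 2L * as.integer(ceiling(ext / spacing)) +
    2L * spec$grid_margin_vox + 1L
  dims <- if (is.null(spec$grid_dims)) need else as.integer(spec$grid_dims)
  if (any(dims < need)) {
    stop(sprintf("lesion exceeds grid: need at least %s voxels, have %s",
                 paste(need, collapse = "x"), paste(dims, collapse = "x")))
  }
  centre <- (dims - 1) / 2 * spacing
  # directional random-bump field on the unit sphere
  K <- 8L
  u <- matrix(rnorm(3 * K), K, 3)
  u <- u / sqrt(rowSums(u^2))
  w <- rnorm(K)
  cx <- (seq_len(dims[1]) - 1) * spacing[1] - centre[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2] - centre[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3] - centre[3]
  X <- array(cx, dims)
  Y <- aperm(array(cy, dims[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(cz, dims[c(3, 2, 1)]), c(3, 2, 1))
  nrm <- sqrt(X^2 + Y^2 + Z^2)
  nrm[nrm == 0] <- 1e-9
  bump <- array(0, dims)
  for (k in seq_len(K)) {
    ca <- (X * u[k, 1] + Y * u[k, 2] + Z * u[k, 3]) / nrm
    bump <- bump + w[k] * exp((ca - 1) / 0.3)
  }
  bump <- (bump - mean(bump)) / max(sd(bump), 1e-12)
  # ellipsoid radius along each voxel direction, modulated by the bump field
  re <- nrm / sqrt((X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2)
  radius <- re * pmax(1 + irr * 0.35 * bump, 0.2)
  mask_arr <- nrm <= radius
  if (!any(mask_arr)) { # guarantee at least the centre voxel
    ci <- (dims + 1) %/% 2
    mask_arr[ci[1], ci[2], ci[3]] <- TRUE
  }
  # background: low-density brain-like texture ~0-40 HU
  bg <- 20 + 8 * grf_unit(dims, 3, spacing)
  vol <- pmin(pmax(bg, 0), 40)
  if (het > 0) {
    interior <- mean_hu + het * grf_unit(dims, spec$texture_corr_mm, spacing)
  } else {
    interior <- array(mean_hu, dims)
  }
  vol[mask_arr] <- interior[mask_arr]
  mask <- lesion_mask(mask_arr, spacing)
  measured <- mask_volume_cm3(mask)
  list(volume = image_volume(vol, spacing), mask = mask,
       latents = list(volume_cm3 = measured, log_volume = log(measured),
                      mean_hu = mean_hu, heterogeneity = het,
                      irregularity = irr, slice_thickness = thick))
}

#' Perturbed repeat segmentations
#'
#' Emulates inter-/intra-rater segmentation variability: the mask boundary is
#' shifted by a smooth random field added to its signed Euclidean distance
#' transform (mm), i.e. random local dilations/erosions of magnitude on the
#' order of `jitter_mm`. `jitter_mm = 0` returns exact copies; the expected
#' Dice overlap with the input decreases as `jitter_mm` grows.
#'
#' @param mask a non-empty [lesion_mask()].
#' @param n_reps number of replicates (>= 1).
#' @param jitter_mm boundary perturbation scale in mm (>= 0).
#' @param seed integer seed.
#' @return list of `n_reps` [lesion_mask()]s.
#' @export
generate_repeat_masks <- function(mask, n_reps = 2L, jitter_mm = 1, seed = 1L) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (sum(mask$voxels) == 0L) stop("mask is empty")
  if (n_reps < 1L) stop("`n_reps` must be >= 1")
  if (jitter_mm < 0) stop("`jitter_mm` must be >= 0")
  if (jitter_mm == 0) {
    return(replicate(n_reps, mask, simplify = FALSE))
  }
  d <- dim(mask$voxels)
  set.seed(seed)
  m <- mask$voxels
  d_in <- sqrt(edt_sq_cpp(as.integer(m), as.integer(d),
                          as.numeric(mask$spacing)))
  d_out <- sqrt(edt_sq_cpp(as.integer(1L - m), as.integer(d),
                           as.numeric(mask$spacing)))
  signed <- array(d_in - d_out, d) # positive inside, mm
  lapply(seq_len(n_reps), function(r) {
    eta <- grf_unit(d, 4, mask$spacing) * (jitter_mm / 2)
    rep_arr <- (signed + eta) > 0
    if (!any(rep_arr)) rep_arr <- m == 1L
    lesion_mask(rep_arr, mask$spacing)
  })
}

#' Dice overlap of two masks
#' @param a,b aligned [lesion_mask()]s.
#' @return Dice coefficient between 0 and 1.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a$voxels); sb <- sum(b$voxels)
  if (sa + sb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (sa + sb)
}

# --- planted-signal calibration -------------------------------------------

# draw n latent vectors from the spec's marginals (no images), standardized
draw_latent_scores <- function(spec, n) {
  v <- exp(rnorm(n, spec$volume_meanlog, spec$volume_sdlog))
  v <- pmin(pmax(v, spec$volume_range_cm3[1]), spec$volume_range_cm3[2])
  lat <- cbind(log_volume = log(v),
               mean_hu = rnorm(n, spec$mean_hu_mean, spec$mean_hu_sd),
               heterogeneity = exp(rnorm(n, spec$het_meanlog, spec$het_sdlog)),
               irregularity = rbeta(n, spec$irregularity_shape1,
                                    spec$irregularity_shape2))
  scale(lat)
}

mann_whitney_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# calibrate (kappa, alpha) so that P(HE) has the target prevalence and the
# true log-odds score discriminates at auc_target; Monte-Carlo inversion
calibrate_planted_effects <- function(spec, seed, n_mc = 100000L) {
  beta <- spec$planted_feature_effects
  set.seed(patient_seed(seed, 0L, 999L))
  z <- draw_latent_scores(spec, n_mc)
  s <- drop(z[, names(beta), drop = FALSE] %*% beta)
  if (sum(abs(beta)) == 0 || spec$auc_target <= 0.5) {
    return(list(kappa = 0, alpha = qlogis(spec$he_prevalence),
                latent_centre = attr(z, "scaled:center"),
                latent_scale = attr(z, "scaled:scale"),
                marker_offsets = calibrate_marker_offsets(spec, z)))
  }
  u <- runif(n_mc) # common random numbers across kappa evaluations
  auc_at <- function(kappa) {
    alpha <- uniroot(function(a) mean(plogis(a + kappa * s)) -
                       spec$he_prevalence, c(-30, 30))$root
    y <- as.integer(u < plogis(alpha + kappa * s))
    mann_whitney_auc(s, y)
  }
  kap <- uniroot(function(k) auc_at(exp(k)) - spec$auc_target,
                 c(log(1e-3), log(20)), tol = 1e-3)$root
  kappa <- exp(kap)
  alpha <- uniroot(function(a) mean(plogis(a + kappa * s)) -
                     spec$he_prevalence, c(-30, 30))$root
  list(kappa = kappa, alpha = alpha,
       latent_centre = attr(z, "scaled:center"),
       latent_scale = attr(z, "scaled:scale"),
       marker_offsets = calibrate_marker_offsets(spec, z))
}

# per-marker intercepts such that the population marker prevalence matches
# the spec marginal despite the latent loading (logit-normal mean inflation)
calibrate_marker_offsets <- function(spec, z) {
  pm <- spec$clinical_marginals$marker_probs
  shape_markers <- c("island", "satellite", "irregular_shape")
  vapply(names(pm), function(mk) {
    load <- spec$marker_signal * 0.8 *
      z[, if (mk %in% shape_markers) "irregularity" else "heterogeneity"]
    target <- min(max(pm[[mk]], 1e-4), 1 - 1e-4)
    uniroot(function(c0) mean(plogis(c0 + load)) - target, c(-30, 30))$root
  }, numeric(1))
}

sample_binned <- function(n, breaks, probs) {
  probs <- probs / sum(probs)
  bin <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  lo <- breaks[bin]; hi <- breaks[bin + 1] - 1
  lo + floor(runif(n) * (hi - lo + 1))
}

rgamma_msd <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Generate the tabular patient record for a cohort
#'
#' Given the latent lesion properties of every patient, draws the clinical
#' variables from the spec's marginals, the HE label from the calibrated
#' logistic model on standardized latents, a 24-h follow-up volume consistent
#' with the volume-based HE rule ([label_he()]), the eight visual markers as
#' Bernoulli draws tied to latent irregularity (shape markers) and
#' heterogeneity (density markers), and an ordinal 0--6 mRS positively loaded
#' on HE, NIHSS and baseline lesion volume with ~`mrs_missing` missingness.
#'
#' @param spec a [cohort_spec()].
#' @param latents data frame / tibble with columns `log_volume`, `mean_hu`,
#'   `heterogeneity`, `irregularity`, `volume_cm3`, `slice_thickness` (one
#'   row per patient, as produced by [generate_lesion()]).
#' @param seed integer run seed.
#' @return tibble with one row per patient: clinical variables, markers,
#'   volumes, `he`, `mrs`, `true_logodds`.
#' @export
generate_tabular <- function(spec, latents, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  need <- c("log_volume", "mean_hu", "heterogeneity", "irregularity",
            "volume_cm3", "slice_thickness")
  missing_vars <- setdiff(need, names(latents))
  if (length(missing_vars)) {
    stop("latent properties missing: ", paste(missing_vars, collapse = ", "))
  }
  cm <- spec$clinical_marginals
  need_cm <- c("glucose", "platelets", "onset_to_ct", "male_frac",
               "nihss_bins", "gcs_bins", "marker_probs", "mrs_probs")
  miss_cm <- setdiff(need_cm, names(cm))
  if (length(miss_cm)) {
    stop("clinical marginals missing: ", paste(miss_cm, collapse = ", "))
  }
  n <- nrow(latents)
  cal <- calibrate_planted_effects(spec, seed)
  set.seed(patient_seed(seed, 0L, 2L))
  beta <- spec$planted_feature_effects
  zc <- cal$latent_centre; zs <- cal$latent_scale
  zmat <- vapply(names(beta), function(v) {
    (latents[[v]] - zc[[v]]) / zs[[v]]
  }, numeric(n))
  s <- drop(zmat %*% beta) * cal$kappa
  p_he <- plogis(cal$alpha + s)
  he <- as.integer(runif(n) < p_he)
  # follow-up volume reproducing the drawn label under the volume rule
  base_v <- latents$volume_cm3
  thr <- pmin(0.33 * base_v, 6)
  growth <- ifelse(he == 1,
                   thr * (1.05 + stats::rexp(n, rate = 1 / 0.8)),
                   thr * runif(n, -0.3, 0.95))
  followup <- base_v + growth
  # clinical marginals
  nihss <- sample_binned(n, cm$nihss_bins$breaks, cm$nihss_bins$probs)
  gcs <- sample_binned(n, cm$gcs_bins$breaks, cm$gcs_bins$probs)
  z_irr <- (latents$irregularity - zc[["irregularity"]]) / zs[["irregularity"]]
  z_het <- (latents$heterogeneity - zc[["heterogeneity"]]) / zs[["heterogeneity"]]
  shape_markers <- c("island", "satellite", "irregular_shape")
  markers <- vapply(names(cm$marker_probs), function(mk) {
    load <- if (mk %in% shape_markers) z_irr else z_het
    pm <- plogis(cal$marker_offsets[[mk]] + spec$marker_signal * 0.8 * load)
    as.integer(runif(n) < pm)
  }, integer(n))
  colnames(markers) <- names(cm$marker_probs)
  # ordinal mRS: latent loaded on HE, NIHSS and baseline volume (larger
  # hematomas carry worse functional outcome), cut at marginal quantiles
  z_nihss <- as.numeric(scale(nihss))
  z_vol <- (latents$log_volume - zc[["log_volume"]]) / zs[["log_volume"]]
  mrs_lat <- 0.9 * he + 0.5 * z_nihss + 0.6 * z_vol + rnorm(n)
  cuts <- quantile(mrs_lat, cumsum(cm$mrs_probs)[-length(cm$mrs_probs)],
                   type = 7)
  mrs <- as.integer(cut(mrs_lat, c(-Inf, cuts, Inf), labels = FALSE)) - 1L
  mrs[runif(n) < spec$mrs_missing] <- NA_integer_
  tibble::tibble(
    sex_male = as.integer(runif(n) < cm$male_frac),
    nihss = nihss, gcs = gcs,
    platelets = rgamma_msd(n, cm$platelets$mean, cm$platelets$sd),
    glucose = rgamma_msd(n, cm$glucose$mean, cm$glucose$sd),
    onset_to_ct = rgamma_msd(n, cm$onset_to_ct$mean, cm$onset_to_ct$sd),
    tibble::as_tibble(markers),
    baseline_volume = base_v, followup_volume = followup,
    he = he, mrs = mrs,
    slice_thickness = latents$slice_thickness,
    true_logodds = cal$alpha + s)
}

#' Simulate a full cohort (latents + tabular record + cohort split)
#'
#' Generates every patient's lesion (to obtain the measured latent
#' properties), draws the tabular record with [generate_tabular()], and
#' randomly allocates patients in equal parts to a discovery and an
#' independent validation cohort. Images are regenerated on demand by
#' [generate_lesion()] / [extract_cohort_features()] rather than stored.
#'
#' @inheritParams generate_tabular
#' @return tibble with `patient_id`, latent columns, the tabular record and a
#'   `cohort` factor (`discovery` / `validation`).
#' @export
simulate_cohort <- function(spec, seed) {
  lat <- purrr::map_dfr(seq_len(spec$n_patients), function(i) {
    tibble::as_tibble(generate_lesion(spec, i, seed)$latents)
  })
  tab <- generate_tabular(spec, lat, seed)
  out <- dplyr::bind_cols(tibble::tibble(patient_id = seq_len(spec$n_patients)),
                          lat[c("log_volume", "mean_hu", "heterogeneity",
                                "irregularity")],
                          tab)
  allocate_cohorts(out, seed)
}

#' Randomly allocate patients to discovery and validation cohorts
#'
#' Uniformly random permutation split into two halves whose sizes differ by
#' at most one (897 patients give 449/448); no patient appears in both.
#'
#' @param patients tibble of patients (>= 2 rows).
#' @param seed integer seed.
#' @return the input with a `cohort` column (`discovery`/`validation`).
#' @export
allocate_cohorts <- function(patients, seed) {
  n <- nrow(patients)
  if (n < 2) stop("need at least 2 patients")
  set.seed(patient_seed(seed, 0L, 3L))
  perm <- sample.int(n)
  n_disc <- ceiling(n / 2)
  cohort <- rep("validation", n)
  cohort[perm[seq_len(n_disc)]] <- "discovery"
  patients$cohort <- factor(cohort, levels = c("discovery", "validation"))
  patients
}
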