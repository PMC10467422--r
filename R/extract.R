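#' Extraction configuration
#'
#' All tunables of the image pipeline in one object. Defaults follow the
#' pipeline's published settings where stated (isotropic 1 mm resampling,
#' 1--200 HU re-segmentation, coiflet-1 wavelets, LoG sigmas 2/4/6 mm) and
#' documented package choices where not (bin width 25, GLDM alpha 0,
#' direction-averaged GLCM/GLRLM aggregation).
#'
#' @param bin_width,bin_count passed to [discretization_config()].
#' @param sigmas LoG scales in mm.
#' @param wavelet include the eight wavelet sub-bands.
#' @param resample resample to `new_spacing` before filtering.
#' @param new_spacing target isotropic spacing, mm.
#' @param hu_range re-segmentation HU window `c(lo, hi)`.
#' @param crop_margin voxels of context retained around the lesion bounding
#'   box after resampling; bounds the filters' effective support for speed.
#' @param gldm_alpha GLDM dependence threshold.
#' @return list with class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 25, bin_count = NULL,
                              sigmas = c(2, 4, 6), wavelet = TRUE,
                              resample = TRUE, new_spacing = c(1, 1, 1),
                              hu_range = c(1, 200), crop_margin = 12L,
                              gldm_alpha = 0L) {
  structure(list(
    discretization = discretization_config(bin_width, bin_count),
    sigmas = sigmas, wavelet = wavelet, resample = resample,
    new_spacing = new_spacing, hu_range = hu_range,
    crop_margin = as.integer(crop_margin), gldm_alpha = as.integer(gldm_alpha)
  ), class = "extraction_config")
}

TEXTURE_KINDS <- c("glcm", "glrlm", "glszm", "ngtdm", "gldm")

#' Preprocess one patient: resample, filter, re-segment
#'
#' Deterministic chain: isotropic B-spline resampling of image and mask, crop
#' to the lesion bounding box plus `crop_margin` voxels, derivative-image
#' generation (original + 8 wavelet sub-bands + LoG scales), then HU
#' re-segmentation of the mask on the original image to define the feature
#' region for every image. Filtering precedes masking because derivative
#' intensities are no longer HU.
#'
#' @inheritParams resample_isotropic
#' @param config an [extraction_config()].
#' @return list: `images` (named list of 12 `image_volume`s), `mask` (the
#'   re-segmented [lesion_mask()]), and `excluded` (TRUE with a `reason` if
#'   the re-segmented mask is empty).
#' @export
preprocess_patient <- function(volume, mask, config = extraction_config()) {
  check_aligned(volume, mask)
  if (config$resample &&
      max(abs(volume$spacing - config$new_spacing)) > 1e-9) {
    rs <- resample_isotropic(volume, mask, config$new_spacing)
    volume <- rs$volume; mask <- rs$mask
  }
  if (sum(mask$voxels) == 0L) {
    return(list(images = NULL, mask = mask, excluded = TRUE,
                reason = "empty mask after resampling"))
  }
  bbox <- mask_bbox(mask$voxels, margin = config$crop_margin)
  vol_c <- image_volume(crop_to_bbox(volume$voxels, bbox), volume$spacing)
  msk_c <- lesion_mask(crop_to_bbox(mask$voxels, bbox), mask$spacing)
  images <- if (config$wavelet) {
    derivative_images(vol_c, config$sigmas)
  } else {
    c(list(original = vol_c), log_bank(vol_c, config$sigmas))
  }
  mask_rs <- resegment_mask(vol_c, msk_c, config$hu_range[1], config$hu_range[2])
  if (isTRUE(attr(mask_rs, "empty"))) {
    return(list(images = images, mask = mask_rs, excluded = TRUE,
                reason = sprintf("no lesion voxel in [%g, %g] HU",
                                 config$hu_range[1], config$hu_range[2])))
  }
  list(images = images, mask = mask_rs, excluded = FALSE)
}

features_one_image <- function(image, mask, config) {
  vals <- image$voxels[mask$voxels == 1L]
  fo <- first_order_features(vals, config$discretization,
                             voxel_volume = prod(image$spacing))
  # discretize once, reuse the levels array for all five texture families;
  # restrict to the mask bounding box + 1 (level-0 surround is inert)
  la <- levels_array(image$voxels, mask$voxels, config$discretization)
  bb <- mask_bbox(mask$voxels, margin = 1L)
  lev_arr <- crop_to_bbox(la$levels, bb)
  lev <- as.integer(lev_arr)
  d <- as.integer(dim(lev_arr))
  ng <- la$ng
  np <- length(vals)
  mk <- function(kind, mat) {
    structure(list(kind = kind, matrix = mat, n_gray_levels = ng,
                   n_voxels = np), class = "texture_matrix")
  }
  raw <- glcm_cpp(lev, d, DIRECTIONS_13, ng)
  raw <- array(raw, c(ng, ng, nrow(DIRECTIONS_13)))
  for (k in seq_len(dim(raw)[3])) raw[, , k] <- raw[, , k] + t(raw[, , k])
  maxrun <- max(d)
  rlm <- array(glrlm_cpp(lev, d, DIRECTIONS_13, ng, maxrun),
               c(ng, maxrun, nrow(DIRECTIONS_13)))
  used <- max(c(1L, which(apply(rlm, 2, sum) > 0)))
  rlm <- rlm[, seq_len(used), , drop = FALSE]
  zones <- glszm_zones_cpp(lev, d)
  szm <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones))) {
    szm[zones[r, 1], zones[r, 2]] <- szm[zones[r, 1], zones[r, 2]] + 1
  }
  dm <- gldm_cpp(lev, d, config$gldm_alpha)
  dm <- dm[, seq_len(max(which(colSums(dm) > 0))), drop = FALSE]
  tms <- list(glcm = mk("glcm", raw), glrlm = mk("glrlm", rlm),
              glszm = mk("glszm", szm), ngtdm = mk("ngtdm", ngtdm_cpp(lev, d, ng)),
              gldm = mk("gldm", dm))
  tex <- unlist(lapply(TEXTURE_KINDS, function(kind) {
    v <- texture_features(tms[[kind]])
    names(v) <- paste0(kind, "_", names(v))
    v
  }))
  c(stats::setNames(fo, paste0("firstorder_", names(fo))), tex)
}

#' Extract the full radiomic feature vector
#'
#' Computes 14 shape features once from the re-segmented mask geometry, plus
#' 18 first-order and 75 texture features on each of the 12 images
#' (original + 11 derivatives): 14 + 12 x 93 = 1,130 named features. Names
#' follow `<imageLabel>_<class>_<FeatureName>` and are returned in
#' lexicographic order (C locale), giving a stable column layout.
#'
#' @inheritParams preprocess_patient
#' @param preprocessed optionally, the result of [preprocess_patient()]
#'   (bypasses `volume`/`mask`).
#' @return named numeric vector of 1,130 finite values, or `NULL` with a
#'   warning if the patient is excluded (empty re-segmented mask).
#' @export
extract_features <- function(volume = NULL, mask = NULL,
                             config = extraction_config(),
                             preprocessed = NULL) {
  pp <- if (is.null(preprocessed)) {
    preprocess_patient(volume, mask, config)
  } else preprocessed
  if (isTRUE(pp$excluded)) {
    warning("patient excluded: ", pp$reason)
    return(NULL)
  }
  shape <- shape_features(pp$mask)
  out <- c(stats::setNames(shape, paste0("original_shape_", names(shape))),
           unlist(lapply(names(pp$images), function(lab) {
             v <- features_one_image(pp$images[[lab]], pp$mask, config)
             stats::setNames(v, paste0(lab, "_", names(v)))
           })))
  out[!is.finite(out)] <- 0
  out[order(names(out), method = "radix")]
}

#' Simulate a cohort and extract its features in one pass
#'
#' Generates each lesion once, extracts the full feature vector, and builds
#' the tabular record and cohort split from the collected latent properties.
#' Equivalent to [simulate_cohort()] + [extract_cohort_features()] but
#' without regenerating the image data.
#'
#' @inheritParams extract_cohort_features
#' @return list: `cohort` tibble (patients with successful extraction) and
#'   `features` tibble.
#' @export
simulate_and_extract <- function(spec, seed, config = extraction_config()) {
  n <- spec$n_patients
  lat_rows <- vector("list", n)
  feat_rows <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    les <- generate_lesion(spec, i, seed)
    lat_rows[[i]] <- tibble::as_tibble(les$latents)
    fv <- tryCatch(extract_features(les$volume, les$mask, config),
                   warning = function(w) NULL)
    if (!is.null(fv)) {
      kept[i] <- TRUE
      feat_rows[[i]] <- fv
    }
  }
  lat <- dplyr::bind_rows(lat_rows)
  tab <- generate_tabular(spec, lat, seed)
  cohort <- dplyr::bind_cols(tibble::tibble(patient_id = seq_len(n)),
                             lat[c("log_volume", "mean_hu", "heterogeneity",
                                   "irregularity")],
                             tab)
  cohort <- allocate_cohorts(cohort, seed)
  features <- dplyr::bind_cols(
    tibble::tibble(patient_id = which(kept)),
    tibble::as_tibble(do.call(rbind, feat_rows[kept])))
  list(cohort = cohort[kept, ], features = features)
}

#' Extract features for a whole synthetic cohort
#'
#' Regenerates each patient's lesion deterministically from the cohort
#' specification and runs the full extraction, returning a tidy feature table
#' (one row per patient, 1,130 feature columns). Excluded patients (empty
#' re-segmented mask) are dropped with a message.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer run seed (same semantics as [simulate_cohort()]).
#' @param config an [extraction_config()].
#' @param patient_ids optional subset of patient indices.
#' @param jitter_mm if > 0, features are extracted from a perturbed repeat
#'   segmentation instead of the primary mask (used for stability screening);
#'   `repeat_id` distinguishes replicates.
#' @param repeat_id integer replicate label (enters the perturbation RNG).
#' @return tibble: `patient_id` plus one column per feature.
#' @export
extract_cohort_features <- function(spec, seed, config = extraction_config(),
                                    patient_ids = NULL, jitter_mm = 0,
                                    repeat_id = 0L) {
  if (is.null(patient_ids)) patient_ids <- seq_len(spec$n_patients)
  rows <- vector("list", length(patient_ids))
  kept <- logical(length(patient_ids))
  for (k in seq_along(patient_ids)) {
    i <- patient_ids[k]
    les <- generate_lesion(spec, i, seed)
    msk <- les$mask
    if (jitter_mm > 0) {
      msk <- generate_repeat_masks(msk, n_reps = 1L, jitter_mm = jitter_mm,
                                   seed = patient_seed(seed, i, 77L + repeat_id))[[1]]
    }
    fv <- tryCatch(extract_features(les$volume, msk, config),
                   warning = function(w) NULL)
    if (is.null(fv)) next
    kept[k] <- TRUE
    rows[[k]] <- fv
  }
  if (!all(kept)) {
    message(sum(!kept), " patient(s) excluded during extraction")
  }
  ids <- patient_ids[kept]
  mat <- do.call(rbind, rows[kept])
  dplyr::bind_cols(tibble::tibble(patient_id = ids),
                   tibble::as_tibble(mat))
}
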