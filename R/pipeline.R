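#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of a full run: the cohort spec and seed, extraction
#' settings, screening thresholds, the harmonization switch (default off,
#' matching the main analysis; the ComBat iteration is a sensitivity
#' variant), the signature list, and the recall floor of the operating
#' threshold.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer run seed; every random draw derives from it.
#' @param extraction an [extraction_config()].
#' @param icc_threshold,r_threshold screening thresholds.
#' @param harmonize logical; apply ComBat (slice-thickness batches, fit on
#'   discovery) to the screened radiomic features.
#' @param signatures which signatures to fit.
#' @param recall_floor threshold rule for report metrics.
#' @param n_stability number of discovery patients used for the
#'   segmentation-stability analysis.
#' @param stability_reps perturbed repeat segmentations per stability patient.
#' @param jitter_mm boundary perturbation scale of the repeat segmentations.
#' @param nfolds stratified CV folds for the LASSO.
#' @param out_dir optional directory for report tables and the run manifest.
#' @return list with class `he_run_config`.
#' @export
he_run_config <- function(spec = compact_cohort_spec(), seed = 1L,
                          extraction = extraction_config(),
                          icc_threshold = 0.90, r_threshold = 0.80,
                          harmonize = FALSE, signatures = SIGNATURE_NAMES,
                          recall_floor = 0.8, n_stability = 40L,
                          stability_reps = 2L, jitter_mm = 1,
                          nfolds = 10L, out_dir = NULL) {
  structure(list(spec = spec, seed = as.integer(seed), extraction = extraction,
                 icc_threshold = icc_threshold, r_threshold = r_threshold,
                 harmonize = harmonize, signatures = signatures,
                 recall_floor = recall_floor,
                 n_stability = as.integer(n_stability),
                 stability_reps = as.integer(stability_reps),
                 jitter_mm = jitter_mm, nfolds = as.integer(nfolds),
                 out_dir = out_dir),
            class = "he_run_config")
}

# assemble the standardized, imputed model table used by all signatures
prepare_model_data <- function(cohort, features, radiomics_features,
                               harmonize = FALSE) {
  data <- dplyr::inner_join(cohort, features, by = "patient_id")
  disc <- data[data$cohort == "discovery", ]
  combat <- NULL
  if (harmonize) {
    combat <- combat_fit(disc[c("patient_id", radiomics_features)],
                         disc$slice_thickness)
    data[radiomics_features] <-
      combat_apply(data[c("patient_id", radiomics_features)], combat,
                   data$slice_thickness)[radiomics_features]
    disc <- data[data$cohort == "discovery", ]
  }
  imput <- fit_imputation(disc, c(CLINICAL_VARS, "onset_to_ct"))
  data <- impute_apply(data, imput)
  data$bat <- bat_score(data$blend, data$hypodensity, data$onset_to_ct)
  std_vars <- c(radiomics_features, setdiff(CLINICAL_VARS, "sex_male"),
                "onset_to_ct", "bat")
  std <- fit_standardization(data[data$cohort == "discovery", ],
                             variables = c(std_vars, "sex_male",
                                           VISUAL_MARKERS))
  data <- standardize_apply(data, std)
  list(data = data, standardization = std, imputation = imput,
       combat = combat)
}

#' Run the full pipeline: simulate, extract, screen, fit, evaluate
#'
#' Executes all stages in order on a synthetic cohort: cohort simulation,
#' per-patient feature extraction (1,130 features), segmentation-stability
#' and collinearity screening (stability ICC on a discovery subsample with
#' perturbed repeat segmentations), optional ComBat harmonization, candidate
#' assembly with discovery-fit standardization/imputation, LASSO signature
#' fitting, and the evaluation report. Rerunning with the same configuration
#' reproduces all numeric outputs exactly.
#'
#' @param config an [he_run_config()].
#' @return `he_run` object: `cohort`, `features`, `screening`, `signatures`,
#'   `report`, `prepared` (model data and fit-on-discovery parameter
#'   objects), `manifest`.
#' @export
run_pipeline <- function(config = he_run_config()) {
  stopifnot(inherits(config, "he_run_config"))
  spec <- config$spec
  seed <- config$seed
  se <- simulate_and_extract(spec, seed, config$extraction)
  cohort <- se$cohort
  features <- se$features
  n_excluded <- spec$n_patients - nrow(cohort)
  # stability screening on a discovery subsample
  disc_ids <- cohort$patient_id[cohort$cohort == "discovery"]
  set.seed(patient_seed(seed, 0L, 4L))
  stab_ids <- sort(sample(disc_ids, min(config$n_stability, length(disc_ids))))
  rep_tables <- c(
    list(features[features$patient_id %in% stab_ids, ]),
    lapply(seq_len(config$stability_reps), function(r) {
      extract_cohort_features(spec, seed, config$extraction,
                              patient_ids = stab_ids,
                              jitter_mm = config$jitter_mm, repeat_id = r)
    }))
  screening <- screen_features(
    features[features$patient_id %in% disc_ids, ],
    rep_tables, config$icc_threshold, config$r_threshold)
  radiomics_features <- screening$retained_collinearity
  prep <- prepare_model_data(cohort, features, radiomics_features,
                             harmonize = config$harmonize)
  disc <- prep$data[prep$data$cohort == "discovery", ]
  signatures <- fit_all_signatures(disc, disc$he, radiomics_features,
                                   seed = patient_seed(seed, 0L, 5L),
                                   nfolds = config$nfolds,
                                   signatures = config$signatures)
  report <- build_report(signatures, prep$data, config$recall_floor)
  manifest <- list(
    seed = seed, n_patients = spec$n_patients, n_excluded = n_excluded,
    n_discovery = sum(cohort$cohort == "discovery"),
    n_validation = sum(cohort$cohort == "validation"),
    he_prevalence_observed = mean(cohort$he),
    n_features = length(feature_cols(features)),
    n_retained_stability = length(screening$retained_stability),
    n_retained_collinearity = length(radiomics_features),
    harmonized = config$harmonize,
    signatures = names(signatures),
    n_selected = vapply(signatures, function(s) length(s$variables),
                        integer(1)))
  run <- structure(list(cohort = cohort, features = features,
                        screening = screening, signatures = signatures,
                        report = report, prepared = prep,
                        manifest = manifest, config = config),
                   class = "he_run")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  run
}

#' @export
print.he_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<he_run> %d patients (%d/%d split, %d excluded), ",
                     "%d features -> %d stable -> %d modelled\n"),
              m$n_discovery + m$n_validation, m$n_discovery, m$n_validation,
              m$n_excluded, m$n_features, m$n_retained_stability,
              m$n_retained_collinearity))
  print(x$report)
  invisible(x)
}
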