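#' Hematoma-expansion label from baseline and follow-up volumes
#'
#' HE is positive when the 24-h follow-up hematoma volume exceeds baseline by
#' more than 33% or by more than 6 ml. Missing follow-up gives a missing
#' label (such patients are excluded from HE modelling).
#'
#' @param baseline_volume,followup_volume volumes in cm^3; baseline > 0.
#' @return integer vector (0/1, or `NA` where follow-up is missing).
#' @export
label_he <- function(baseline_volume, followup_volume) {
  if (any(baseline_volume <= 0, na.rm = TRUE)) {
    stop("baseline volume must be > 0")
  }
  growth <- followup_volume - baseline_volume
  as.integer(growth / baseline_volume > 0.33 | growth > 6)
}

#' BAT score
#'
#' Published 0--5 visual risk score of hematoma expansion: blend sign 1
#' point, hypodensity 2 points, onset-to-CT under 2.5 h (150 min) 2 points.
#'
#' @param blend,hypodensity binary markers (0/1).
#' @param onset_to_ct minutes from symptom onset to the baseline CT (> 0).
#' @return integer 0--5 (`NA` propagates from missing markers).
#' @export
bat_score <- function(blend, hypodensity, onset_to_ct) {
  if (any(onset_to_ct <= 0, na.rm = TRUE)) stop("onset_to_ct must be > 0")
  as.integer(1L * blend + 2L * hypodensity + 2L * (onset_to_ct < 150))
}

VISUAL_MARKERS <- c("blend", "hypodensity", "swirl", "black_hole",
                    "fluid_level", "island", "satellite", "irregular_shape")
CLINICAL_VARS <- c("sex_male", "nihss", "gcs", "platelets", "glucose")

#' @rdname assemble_candidates
#' @export
SIGNATURE_NAMES <- c("radiomics", "visual", "clinical", "bat",
                     "radiomics_visual", "radiomics_clinical", "radiomics_bat",
                     "radiomics_visual_clinical",
                     "select_radiomics_visual", "select_radiomics_clinical",
                     "select_radiomics_visual_clinical")

#' Candidate variable sets for the eleven signatures
#'
#' Returns the model matrix for a named signature: radiomics (screened
#' features), visual (8 markers), clinical (sex, NIHSS, GCS, platelets,
#' glucose), the BAT score, their combinations, and the "select radiomics"
#' variants that supply only the features selected by the fitted radiomics
#' signature. Onset-to-CT time is appended to every candidate set except
#' those containing the BAT score (which already encodes it).
#'
#' @param signature_name one of `SIGNATURE_NAMES`.
#' @param data tibble holding screened radiomic feature columns, the visual
#'   markers, clinical variables, `onset_to_ct` and `bat` (all already
#'   standardized/imputed with discovery parameters).
#' @param radiomics_features character: screened radiomic feature names.
#' @param select_features character: features selected by the fitted
#'   radiomics signature (required for `select_radiomics_*`).
#' @return numeric matrix (patients x candidate variables).
#' @export
assemble_candidates <- function(signature_name, data, radiomics_features,
                                select_features = NULL) {
  if (!signature_name %in% SIGNATURE_NAMES) {
    stop("unknown signature '", signature_name, "'; valid names: ",
         paste(SIGNATURE_NAMES, collapse = ", "))
  }
  if (startsWith(signature_name, "select_radiomics") &&
      is.null(select_features)) {
    stop("`select_features` (radiomics-signature selection) required for ",
         signature_name)
  }
  vars <- switch(signature_name,
    radiomics = c(radiomics_features, "onset_to_ct"),
    visual = c(VISUAL_MARKERS, "onset_to_ct"),
    clinical = c(CLINICAL_VARS, "onset_to_ct"),
    bat = "bat",
    radiomics_visual = c(radiomics_features, VISUAL_MARKERS, "onset_to_ct"),
    radiomics_clinical = c(radiomics_features, CLINICAL_VARS, "onset_to_ct"),
    radiomics_bat = c(radiomics_features, "bat"),
    radiomics_visual_clinical = c(radiomics_features, VISUAL_MARKERS,
                                  CLINICAL_VARS, "onset_to_ct"),
    select_radiomics_visual = c(select_features, VISUAL_MARKERS, "onset_to_ct"),
    select_radiomics_clinical = c(select_features, CLINICAL_VARS, "onset_to_ct"),
    select_radiomics_visual_clinical = c(select_features, VISUAL_MARKERS,
                                         CLINICAL_VARS, "onset_to_ct"))
  absent <- setdiff(vars, names(data))
  if (length(absent)) {
    stop("candidate variables missing from data: ",
         paste(absent, collapse = ", "))
  }
  as.matrix(data[vars])
}

# deterministic stratified fold assignment
stratified_folds <- function(y, nfolds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

#' Fit a LASSO-regularized logistic signature
#'
#' L1-penalized logistic regression over a descending lambda path, with the
#' penalty chosen at the minimum mean cross-validated binomial deviance over
#' `nfolds` stratified folds (strata: HE-positive and HE-negative patients).
#' Inputs are expected pre-standardized with discovery statistics (binary
#' markers unstandardized); the solver's internal re-standardization is
#' disabled. The stored cross-validation AUC is the mean (and SE) of the
#' test-fold AUCs at the chosen lambda.
#'
#' @param X numeric candidate matrix (patients x variables).
#' @param y binary HE labels.
#' @param seed integer; controls the fold assignment.
#' @param nfolds stratified CV folds (default 10).
#' @param name optional signature name.
#' @param nlambda,lambda_min_ratio extent/resolution of the descending lambda
#'   path (60 values down to 0.01 of lambda_max; dense enough that the
#'   CV-deviance minimum is interior in practice).
#' @return `he_signature` object: selected `variables` and `weights`,
#'   `intercept`, `lambda`, `cv_auc_mean`, `cv_auc_se`, `cv_fold_auc`.
#' @export
fit_signature <- function(X, y, seed = 1L, nfolds = 10L, name = NULL,
                          nlambda = 60L, lambda_min_ratio = 0.01) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both HE classes must be present")
  if (length(y) < 2 * nfolds) stop("need at least 2 patients per fold")
  if (min(table(y)) < nfolds) {
    stop("minority class smaller than the number of folds")
  }
  foldid <- stratified_folds(y, nfolds, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          standardize = FALSE, foldid = foldid,
                          type.measure = "deviance", keep = TRUE,
                          nlambda = nlambda, lambda.min.ratio = lambda_min_ratio)
  lam <- cv$lambda.min
  li <- which(cv$lambda == lam)[1]
  preval <- cv$fit.preval[, li]
  fold_auc <- vapply(seq_len(nfolds), function(k) {
    idx <- foldid == k
    if (length(unique(y[idx])) < 2) return(NA_real_)
    mann_whitney_auc(preval[idx], y[idx])
  }, numeric(1))
  fold_auc <- fold_auc[is.finite(fold_auc)]
  cf <- coef(cv, s = lam)
  w <- as.numeric(cf)[-1]
  names(w) <- rownames(cf)[-1]
  sel <- w[w != 0]
  structure(list(name = name, variables = names(sel), weights = sel,
                 intercept = as.numeric(cf)[1], lambda = lam,
                 cv_auc_mean = mean(fold_auc),
                 cv_auc_se = sd(fold_auc) / sqrt(length(fold_auc)),
                 cv_fold_auc = fold_auc, nfolds = nfolds, seed = seed),
            class = "he_signature")
}

#' @export
print.he_signature <- function(x, ...) {
  cat(sprintf("<he_signature%s> %d variable(s), lambda %.4g, CV AUC %.3f (SE %.3f)\n",
              if (is.null(x$name)) "" else paste0(": ", x$name),
              length(x$variables), x$lambda, x$cv_auc_mean, x$cv_auc_se))
  if (length(x$variables)) {
    for (v in x$variables) cat(sprintf("  %-50s %+.4f\n", v, x$weights[[v]]))
  }
  invisible(x)
}

#' Score patients with a fitted signature
#'
#' Linear predictor `intercept + sum(w_i x_i)` on the standardized inputs; a
#' monotone transform of the predicted HE probability, hence rank-equivalent
#' for AUC purposes.
#'
#' @param signature an `he_signature` (or the `bat` pseudo-signature).
#' @param data tibble with all signature variables (post-standardization and
#'   imputation).
#' @return numeric score per row.
#' @export
score_signature <- function(signature, data) {
  stopifnot(inherits(signature, "he_signature"))
  absent <- setdiff(signature$variables, names(data))
  if (length(absent)) {
    stop("signature variables missing: ", paste(absent, collapse = ", "))
  }
  if (length(signature$variables) == 0) {
    return(rep(signature$intercept, nrow(data)))
  }
  X <- as.matrix(data[signature$variables])
  if (anyNA(X)) stop("missing values in signature variables after imputation")
  drop(signature$intercept + X %*% signature$weights)
}

bat_pseudo_signature <- function() {
  structure(list(name = "bat", variables = "bat",
                 weights = c(bat = 1), intercept = 0, lambda = NA_real_,
                 cv_auc_mean = NA_real_, cv_auc_se = NA_real_,
                 cv_fold_auc = NA_real_, nfolds = NA_integer_, seed = NA),
            class = "he_signature")
}

#' Fit all eleven signatures on the discovery cohort
#'
#' Fits the radiomics signature first, then every combined signature; the
#' `select_radiomics_*` variants are two-stage fits supplying only the
#' radiomics signature's selected features. The BAT "signature" is the score
#' itself (no model fitting, no CV AUC).
#'
#' @param data discovery tibble (standardized/imputed candidate variables).
#' @param y binary HE labels for the discovery rows.
#' @param radiomics_features screened radiomic feature names.
#' @param seed,nfolds passed to [fit_signature()].
#' @param signatures subset of `SIGNATURE_NAMES` to fit (default all).
#' @return named list of `he_signature` objects.
#' @export
fit_all_signatures <- function(data, y, radiomics_features, seed = 1L,
                               nfolds = 10L, signatures = SIGNATURE_NAMES) {
  stopifnot(all(signatures %in% SIGNATURE_NAMES))
  out <- list()
  rad <- fit_signature(assemble_candidates("radiomics", data,
                                           radiomics_features),
                       y, seed, nfolds, name = "radiomics")
  sel <- setdiff(rad$variables, "onset_to_ct")
  if (length(sel) == 0) sel <- radiomics_features[1] # degenerate fallback
  for (nm in signatures) {
    out[[nm]] <- if (nm == "radiomics") {
      rad
    } else if (nm == "bat") {
      bat_pseudo_signature()
    } else {
      fit_signature(assemble_candidates(nm, data, radiomics_features,
                                        select_features = sel),
                    y, seed, nfolds, name = nm)
    }
  }
  out
}
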