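#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC from the
#' standard ANOVA decomposition: with mean squares for rows (patients) MSR,
#' columns (repeats) MSC and error MSE over an n x k table,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param ratings numeric matrix, patients x repeated measurements (n >= 2
#'   rows, k >= 2 columns, no missing values).
#' @return scalar in `[-1, 1]`, or `NaN` when the table has zero total
#'   variance (undefined agreement; such features are dropped upstream).
#' @export
icc21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 patients and >= 2 repeats")
  if (anyNA(ratings)) stop("missing values in ratings")
  gm <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- max(sst - ssr - ssc, 0)
  if (sst == 0) return(NaN)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den == 0) return(NaN)
  (msr - mse) / den
}

feature_cols <- function(tbl) setdiff(names(tbl), "patient_id")

#' Segmentation-stability feature filter
#'
#' Retains features whose ICC(2,1) across repeated (perturbed) segmentations
#' of the same patients reaches `icc_threshold`. Features with undefined ICC
#' (zero variance) are dropped.
#'
#' @param tables list of >= 2 feature tibbles (same patients, same feature
#'   columns; one per segmentation replicate), each with a `patient_id`
#'   column used for alignment.
#' @param icc_threshold retention threshold, default 0.90.
#' @return list: `retained` (character), `icc` (named numeric),
#'   `threshold`.
#' @export
stability_filter <- function(tables, icc_threshold = 0.90) {
  if (length(tables) < 2) stop("need >= 2 replicate tables")
  ids <- Reduce(intersect, lapply(tables, function(t) t$patient_id))
  if (length(ids) < 2) stop("need >= 2 common patients")
  feats <- Reduce(intersect, lapply(tables, feature_cols))
  aligned <- lapply(tables, function(t) {
    t[match(ids, t$patient_id), feats, drop = FALSE]
  })
  icc <- vapply(feats, function(f) {
    icc21(vapply(aligned, function(a) a[[f]], numeric(length(ids))))
  }, numeric(1))
  retained <- feats[is.finite(icc) & icc >= icc_threshold]
  list(retained = retained, icc = icc, threshold = icc_threshold)
}

#' Collinearity feature filter
#'
#' Greedy elimination on the pairwise Spearman correlation matrix: while any
#' absolute correlation among retained features exceeds `r_threshold`
#' (default 0.80), the member of the worst pair with the larger mean absolute
#' correlation to all other retained features is dropped (ties broken by
#' dropping the lexicographically later name). Constant features are dropped
#' first.
#'
#' @param tbl feature tibble (optionally with `patient_id`), >= 3 rows.
#' @param r_threshold absolute Spearman correlation threshold.
#' @return list: `retained`, `dropped` (both character), `threshold`.
#' @export
collinearity_filter <- function(tbl, r_threshold = 0.80) {
  feats <- feature_cols(tbl)
  X <- as.matrix(tbl[feats])
  if (nrow(X) < 3) stop("need >= 3 patients")
  const <- feats[apply(X, 2, function(v) max(v) == min(v))]
  if (length(const)) {
    message("dropping ", length(const), " constant feature(s) before screening")
  }
  keepf <- setdiff(feats, const)
  R <- abs(cor(apply(X[, keepf, drop = FALSE], 2, rank), method = "pearson"))
  diag(R) <- 0
  # all offending pairs once, processed from the strongest down
  hi <- which(R > r_threshold & upper.tri(R), arr.ind = TRUE)
  ord <- order(R[hi], decreasing = TRUE)
  hi <- hi[ord, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, length(keepf)), keepf)
  rowsum_abs <- rowSums(R)
  for (r in seq_len(nrow(hi))) {
    i <- hi[r, 1]; j <- hi[r, 2]
    ni <- keepf[i]; nj <- keepf[j]
    if (!alive[ni] || !alive[nj]) next
    k_alive <- sum(alive)
    mi <- rowsum_abs[i] / (k_alive - 1)
    mj <- rowsum_abs[j] / (k_alive - 1)
    drop_name <- if (mi > mj) ni else if (mj > mi) nj else max(ni, nj)
    alive[drop_name] <- FALSE
    di <- match(drop_name, keepf)
    rowsum_abs <- rowsum_abs - R[, di]
  }
  retained <- keepf[alive[keepf]]
  list(retained = retained,
       dropped = c(const, setdiff(keepf, retained)),
       threshold = r_threshold)
}

#' Feature screening wrapper
#'
#' Stability filter followed by collinearity filter; the collinearity step
#' sees only stability-retained features, so the retained sets are nested.
#'
#' @param primary discovery feature tibble (used for collinearity).
#' @param replicate_tables list of replicate feature tibbles (stability).
#' @param icc_threshold,r_threshold filter thresholds.
#' @return `screening_report` list: `n_input`, `retained_stability`,
#'   `retained_collinearity`, `icc_per_feature`, thresholds.
#' @export
screen_features <- function(primary, replicate_tables,
                            icc_threshold = 0.90, r_threshold = 0.80) {
  st <- stability_filter(replicate_tables, icc_threshold)
  col_in <- primary[c("patient_id", intersect(st$retained,
                                              feature_cols(primary)))]
  co <- collinearity_filter(col_in, r_threshold)
  structure(list(n_input = length(feature_cols(primary)),
                 retained_stability = st$retained,
                 retained_collinearity = co$retained,
                 icc_per_feature = st$icc,
                 icc_threshold = icc_threshold,
                 correlation_threshold = r_threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(paste0("<screening_report> %d features -> %d stable ",
                     "(ICC >= %.2f) -> %d non-collinear (|rho| <= %.2f)\n"),
              x$n_input, length(x$retained_stability), x$icc_threshold,
              length(x$retained_collinearity), x$correlation_threshold))
  invisible(x)
}

#' Fit-on-discovery standardization
#'
#' Stores per-variable discovery means and SDs for continuous/ordinal
#' variables; binary (0/1) variables are flagged and passed through
#' unchanged. Applying the parameters to validation rows uses the discovery
#' statistics, never the validation ones.
#'
#' @param tbl discovery tibble.
#' @param variables columns to consider (default: all numeric except
#'   `patient_id`).
#' @return `standardization_params` object.
#' @export
fit_standardization <- function(tbl, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                         "patient_id")
  }
  is_bin <- vapply(variables, function(v) {
    all(tbl[[v]] %in% c(0, 1, NA))
  }, logical(1))
  cont <- variables[!is_bin]
  mu <- vapply(cont, function(v) mean(tbl[[v]], na.rm = TRUE), numeric(1))
  sg <- vapply(cont, function(v) sd(tbl[[v]], na.rm = TRUE), numeric(1))
  zero <- cont[sg == 0 | !is.finite(sg)]
  if (length(zero)) {
    warning("constant variable(s) passed through unstandardized: ",
            paste(zero, collapse = ", "))
    keep <- !(cont %in% zero)
    cont <- cont[keep]; mu <- mu[keep]; sg <- sg[keep]
  }
  structure(list(variables = variables, continuous = cont,
                 binary = variables[is_bin], mean = mu, sd = sg),
            class = "standardization_params")
}

#' @rdname fit_standardization
#' @param params a fitted `standardization_params`.
#' @export
standardize_apply <- function(tbl, params) {
  stopifnot(inherits(params, "standardization_params"))
  absent <- setdiff(c(params$continuous, params$binary), names(tbl))
  if (length(absent)) {
    stop("variables missing from table: ", paste(absent, collapse = ", "))
  }
  for (v in params$continuous) {
    tbl[[v]] <- (tbl[[v]] - params$mean[[v]]) / params$sd[[v]]
  }
  tbl
}

#' Fit-on-discovery median imputation
#'
#' Medians are computed on the discovery cohort's non-missing values and used
#' to fill missing entries in any cohort.
#'
#' @param tbl discovery tibble.
#' @param variables columns to impute.
#' @return `imputation_params` object.
#' @export
fit_imputation <- function(tbl, variables) {
  med <- vapply(variables, function(v) {
    x <- tbl[[v]]
    if (all(is.na(x))) stop("all values missing in discovery for: ", v)
    median(x, na.rm = TRUE)
  }, numeric(1))
  structure(list(variables = variables, medians = med),
            class = "imputation_params")
}

#' @rdname fit_imputation
#' @param params a fitted `imputation_params`.
#' @export
impute_apply <- function(tbl, params) {
  stopifnot(inherits(params, "imputation_params"))
  n_imp <- 0L
  for (v in params$variables) {
    idx <- is.na(tbl[[v]])
    n_imp <- n_imp + sum(idx)
    tbl[[v]][idx] <- params$medians[[v]]
  }
  attr(tbl, "n_imputed") <- n_imp
  tbl
}
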