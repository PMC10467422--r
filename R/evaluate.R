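# midrank placement values of DeLong's method: for each positive score, the
# fraction of negatives it beats (ties 1/2), and vice versa
delong_placements <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC with DeLong variance and 95% CI
#'
#' The AUC is the Mann-Whitney statistic (ties counted 1/2); its variance
#' comes from DeLong's structural components (sample variances of the
#' per-positive and per-negative placement values), and the 95% CI is
#' `auc +/- 1.96 se`, clipped to `[0, 1]`.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary outcomes (0/1), both classes present.
#' @return list: `auc`, `variance`, `ci` (length-2).
#' @export
auc_delong <- function(scores, labels) {
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  pl <- delong_placements(scores, labels)
  m <- length(pl$v10); n <- length(pl$v01)
  v <- (if (m > 1) var(pl$v10) else 0) / m + (if (n > 1) var(pl$v01) else 0) / n
  se <- sqrt(v)
  list(auc = pl$auc, variance = v,
       ci = pmin(pmax(pl$auc + qnorm(0.975) * c(-se, se), 0), 1))
}

#' Paired DeLong test for two AUCs
#'
#' Two-sided z-test on the AUC difference of two scores measured on the same
#' patients, using the paired covariance of DeLong placement values. A
#' zero-variance difference with equal AUCs returns p = 1 by convention.
#'
#' @param scores_a,scores_b paired predictions on identical patients.
#' @param labels binary outcomes (0/1).
#' @return list: `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) stop("scores must be paired")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (vd <= 0) {
    p <- if (abs(d) < 1e-12) 1 else 0
    return(list(p_value = p, auc_a = pa$auc, auc_b = pb$auc,
                z = if (abs(d) < 1e-12) 0 else sign(d) * Inf))
  }
  z <- d / sqrt(vd)
  list(p_value = 2 * pnorm(-abs(z)), auc_a = pa$auc, auc_b = pb$auc, z = z)
}

#' Threshold metrics with a discovery-derived cutoff
#'
#' The operating threshold is the largest cutoff whose discovery-cohort
#' recall is at least `recall_floor` (default 0.8) when predicting positive
#' at `score >= threshold`; among qualifying cutoffs the largest maximizes
#' specificity. The same threshold is then applied to the evaluation cohort.
#' Degenerate cells follow fixed conventions: NPV with no predicted negatives
#' is 1 (the all-positive rule has no false reassurance to measure),
#' precision with no predicted positives is 0.
#'
#' @param scores_discovery,labels_discovery discovery scores and labels.
#' @param scores_eval,labels_eval evaluation scores and labels.
#' @param recall_floor minimum discovery recall in (0, 1].
#' @return list: `threshold`, `precision`, `recall`, `npv`, `f1`.
#' @export
threshold_metrics <- function(scores_discovery, labels_discovery,
                              scores_eval, labels_eval, recall_floor = 0.8) {
  if (recall_floor <= 0 || recall_floor > 1) {
    stop("`recall_floor` must be in (0, 1]")
  }
  pos <- scores_discovery[labels_discovery == 1]
  if (length(pos) == 0) stop("no positive discovery patients")
  cand <- sort(unique(scores_discovery))
  rec <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  ok <- cand[rec >= recall_floor]
  if (length(ok) == 0) stop("recall floor unattainable at any cutoff")
  thr <- max(ok)
  pred <- scores_eval >= thr
  tp <- sum(pred & labels_eval == 1); fp <- sum(pred & labels_eval == 0)
  tn <- sum(!pred & labels_eval == 0); fn <- sum(!pred & labels_eval == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(threshold = thr, precision = precision, recall = recall,
       npv = npv, f1 = f1)
}

#' Spearman association of signature scores with functional outcome
#'
#' Spearman's rho (midranks for ties) between scores and the 90-day modified
#' Rankin Scale; patients with missing mRS are excluded (count reported).
#' The CI uses the Fisher z transform with variance `1.06 / (n - 3)`; the
#' two-sided p-value uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param scores numeric signature scores.
#' @param mrs ordinal 0--6 outcome, may contain `NA`.
#' @return list: `rho`, `ci`, `p_value`, `n`, `n_excluded`.
#' @export
spearman_outcome <- function(scores, mrs) {
  keep <- !is.na(mrs) & !is.na(scores)
  n_exc <- sum(!keep)
  s <- scores[keep]; m <- mrs[keep]
  n <- length(s)
  if (n < 4) stop("need at least 4 patients with observed mRS")
  if (sd(s) == 0 || sd(m) == 0) {
    # constant scores (e.g. an intercept-only signature): undefined rank
    # correlation, reported as missing
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_, n = n, n_excluded = n_exc))
  }
  rho <- cor(rank(s), rank(m))
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- sqrt(1.06 / (n - 3))
  ci <- tanh(z + qnorm(0.975) * c(-se, se))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, ci = ci, p_value = p, n = n, n_excluded = n_exc)
}

#' Evaluation report over all signatures and both cohorts
#'
#' For every fitted signature: CV AUC (discovery folds), AUC with DeLong 95%
#' CI per cohort, threshold metrics (precision/recall/NPV/F1 at the
#' discovery-derived cutoff), Spearman rho against mRS per cohort, and the
#' pairwise DeLong p-value matrix per cohort.
#'
#' @param signatures named list of `he_signature`s.
#' @param data full standardized/imputed tibble with a `cohort` column,
#'   `he` labels and `mrs`.
#' @param recall_floor threshold rule, see [threshold_metrics()].
#' @return `he_report` object: tibbles `performance`, `spearman`; list
#'   `delong` of p-value matrices; `scores` tibble.
#' @export
build_report <- function(signatures, data, recall_floor = 0.8) {
  stopifnot(is.list(signatures), length(signatures) > 0)
  disc <- data[data$cohort == "discovery", ]
  vali <- data[data$cohort == "validation", ]
  scores <- lapply(signatures, function(s) {
    list(discovery = score_signature(s, disc),
         validation = score_signature(s, vali))
  })
  perf <- purrr::map_dfr(names(signatures), function(nm) {
    s <- signatures[[nm]]
    purrr::map_dfr(c("discovery", "validation"), function(co) {
      sc <- scores[[nm]][[co]]
      lab <- if (co == "discovery") disc$he else vali$he
      a <- auc_delong(sc, lab)
      tm <- threshold_metrics(scores[[nm]]$discovery, disc$he, sc, lab,
                              recall_floor)
      tibble::tibble(signature = nm, cohort = co,
                     cv_auc = s$cv_auc_mean, cv_auc_se = s$cv_auc_se,
                     auc = a$auc, auc_lo = a$ci[1], auc_hi = a$ci[2],
                     threshold = tm$threshold, precision = tm$precision,
                     recall = tm$recall, npv = tm$npv, f1 = tm$f1)
    })
  })
  spear <- purrr::map_dfr(names(signatures), function(nm) {
    purrr::map_dfr(c("discovery", "validation"), function(co) {
      sc <- scores[[nm]][[co]]
      mrs <- if (co == "discovery") disc$mrs else vali$mrs
      sp <- spearman_outcome(sc, mrs)
      tibble::tibble(signature = nm, cohort = co, rho = sp$rho,
                     rho_lo = sp$ci[1], rho_hi = sp$ci[2],
                     p_value = sp$p_value, n = sp$n,
                     n_excluded = sp$n_excluded)
    })
  })
  delong <- lapply(c(discovery = "discovery", validation = "validation"),
                   function(co) {
    nms <- names(signatures)
    lab <- if (co == "discovery") disc$he else vali$he
    P <- matrix(NA_real_, length(nms), length(nms),
                dimnames = list(nms, nms))
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (j <= i) next
        P[i, j] <- P[j, i] <- delong_test(scores[[nms[i]]][[co]],
                                          scores[[nms[j]]][[co]], lab)$p_value
      }
    }
    P
  })
  sc_tbl <- purrr::map_dfr(names(signatures), function(nm) {
    tibble::tibble(
      signature = nm,
      cohort = c(rep("discovery", nrow(disc)), rep("validation", nrow(vali))),
      patient_id = c(disc$patient_id, vali$patient_id),
      score = c(scores[[nm]]$discovery, scores[[nm]]$validation))
  })
  structure(list(performance = perf, spearman = spear, delong = delong,
                 scores = sc_tbl, recall_floor = recall_floor),
            class = "he_report")
}

#' @export
print.he_report <- function(x, ...) {
  cat("<he_report>\n")
  print(as.data.frame(x$performance[, c("signature", "cohort", "cv_auc",
                                        "auc", "auc_lo", "auc_hi",
                                        "precision", "recall", "npv", "f1")]),
        digits = 3)
  invisible(x)
}

#' Write the report tables to a directory
#'
#' Emits `performance.csv`, `spearman.csv`, one `delong_<cohort>.csv` per
#' cohort, and `report.json` with full numeric precision.
#'
#' @param report an `he_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "he_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$spearman, file.path(dir, "spearman.csv"),
                   row.names = FALSE)
  for (co in names(report$delong)) {
    utils::write.csv(as.data.frame(report$delong[[co]]),
                     file.path(dir, paste0("delong_", co, ".csv")))
  }
  jsonlite::write_json(list(performance = report$performance,
                            spearman = report$spearman,
                            delong = lapply(report$delong, as.data.frame)),
                       file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
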