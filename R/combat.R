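#' Empirical-Bayes batch harmonization (ComBat), fit on discovery
#'
#' Standard parametric ComBat for per-feature location/scale batch effects,
#' with CT slice thickness as the intended batch variable. Per feature, data
#' are standardized by the pooled (batch-size-weighted) mean and the pooled
#' residual variance around batch means; per-batch location (gamma) and scale
#' (delta^2) estimates are then shrunk toward their across-feature priors
#' (normal for gamma, inverse-gamma for delta^2, moment-matched) by the usual
#' iterative EB solution. No biological covariates are preserved. Parameters
#' are estimated from the discovery cohort only and applied unchanged to any
#' cohort; batches unseen at fit time are rejected.
#'
#' @param tbl feature tibble (optionally with `patient_id`), discovery rows.
#' @param batch vector of batch labels, one per row; at least 2 batches,
#'   each with at least 2 patients.
#' @param conv convergence tolerance of the EB iteration.
#' @return `combat_params` object.
#' @export
combat_fit <- function(tbl, batch, conv = 1e-4) {
  feats <- feature_cols(tbl)
  X <- as.matrix(tbl[feats])
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("singleton batch: ", paste(names(nb)[nb < 2], collapse = ", "))
  }
  n <- nrow(X)
  levs <- levels(batch)
  # batch means and pooled statistics
  bm <- do.call(rbind, lapply(levs, function(l) colMeans(X[batch == l, , drop = FALSE])))
  w <- as.numeric(nb[levs]) / n
  alpha <- drop(w %*% bm)
  resid <- X - bm[as.integer(batch), , drop = FALSE]
  var_pooled <- colSums(resid^2) / n
  var_pooled[var_pooled <= 0] <- 1e-12
  Z <- sweep(sweep(X, 2, alpha), 2, sqrt(var_pooled), `/`)
  gamma_hat <- do.call(rbind, lapply(levs, function(l) colMeans(Z[batch == l, , drop = FALSE])))
  delta_hat <- do.call(rbind, lapply(levs, function(l) {
    apply(Z[batch == l, , drop = FALSE], 2, var)
  }))
  # EB hyper-priors (moment matching across features)
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, var)
  a_prior <- apply(delta_hat, 1, function(d) (2 * var(d) + mean(d)^2) / var(d))
  b_prior <- apply(delta_hat, 1, function(d) {
    (mean(d) * var(d) + mean(d)^3) / var(d)
  })
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_along(levs)) {
    # EB needs across-feature spread; with a degenerate prior keep the raw
    # batch estimates (single-feature tables, identical features)
    if (!is.finite(tau2[b]) || tau2[b] <= 0 ||
        !is.finite(a_prior[b]) || !is.finite(b_prior[b])) next
    nk <- as.numeric(nb[levs[b]])
    zb <- Z[batch == levs[b], , drop = FALSE]
    g_old <- gamma_hat[b, ]; d_old <- delta_hat[b, ]
    repeat {
      g_new <- (tau2[b] * nk * gamma_hat[b, ] + d_old * gamma_bar[b]) /
        (tau2[b] * nk + d_old)
      sum2 <- colSums(sweep(zb, 2, g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (nk / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
  }
  rownames(gamma_star) <- rownames(delta_star) <- levs
  structure(list(features = feats, batches = levs, alpha = alpha,
                 var_pooled = var_pooled, gamma_star = gamma_star,
                 delta_star = delta_star, gamma_hat = gamma_hat,
                 delta_hat = delta_hat),
            class = "combat_params")
}

#' @rdname combat_fit
#' @param params a fitted `combat_params`.
#' @export
combat_apply <- function(tbl, params, batch) {
  stopifnot(inherits(params, "combat_params"))
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), params$batches)
  if (length(unseen)) {
    stop("batch level(s) unseen at fit time: ", paste(unseen, collapse = ", "))
  }
  absent <- setdiff(params$features, names(tbl))
  if (length(absent)) {
    stop("features missing from table: ", paste(absent, collapse = ", "))
  }
  X <- as.matrix(tbl[params$features])
  Z <- sweep(sweep(X, 2, params$alpha), 2, sqrt(params$var_pooled), `/`)
  bi <- match(batch, params$batches)
  adj <- (Z - params$gamma_star[bi, , drop = FALSE]) /
    sqrt(params$delta_star[bi, , drop = FALSE])
  out <- sweep(sweep(adj, 2, sqrt(params$var_pooled), `*`), 2, params$alpha, `+`)
  for (f in params$features) tbl[[f]] <- out[, f]
  tbl
}
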