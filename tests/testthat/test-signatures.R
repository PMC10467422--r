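test_that("HE volume rule matches the printed thresholds", {
  expect_equal(label_he(10, 13.5), 1L)  # 35% > 33%
  expect_equal(label_he(30, 37), 1L)    # 7 ml > 6 ml despite 23% < 33%
  expect_equal(label_he(10, 12), 0L)    # 20% and 2 ml
  expect_true(is.na(label_he(10, NA)))
  expect_error(label_he(0, 5), "baseline")
})

test_that("BAT score combines blend, hypodensity and early imaging", {
  expect_equal(bat_score(0, 0, 180), 0L)
  expect_equal(bat_score(1, 1, 120), 5L)
  expect_equal(bat_score(0, 1, 60), 4L)
  expect_equal(bat_score(1, 0, 150), 1L) # 150 min is not < 2.5 h
  expect_true(is.na(bat_score(NA, 1, 60)))
  expect_error(bat_score(1, 1, 0), "onset_to_ct")
})

fake_model_data <- function(n = 60, n_rad = 5, seed = 1) {
  set.seed(seed)
  rad <- paste0("rad", seq_len(n_rad))
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * n_rad), n, n_rad)))
  names(d) <- rad
  for (mk in hemorad:::VISUAL_MARKERS) d[[mk]] <- rbinom(n, 1, 0.3)
  d$sex_male <- rbinom(n, 1, 0.5)
  d$nihss <- rnorm(n); d$gcs <- rnorm(n); d$platelets <- rnorm(n)
  d$glucose <- rnorm(n); d$onset_to_ct <- rnorm(n); d$bat <- rnorm(n)
  list(data = d, rad = rad)
}

test_that("candidate sets have the documented compositions", {
  fm <- fake_model_data()
  expect_equal(ncol(assemble_candidates("clinical", fm$data, fm$rad)), 6)
  expect_equal(ncol(assemble_candidates("bat", fm$data, fm$rad)), 1)
  expect_equal(colnames(assemble_candidates("bat", fm$data, fm$rad)), "bat")
  expect_equal(ncol(assemble_candidates("radiomics", fm$data, fm$rad)),
               length(fm$rad) + 1)
  expect_equal(ncol(assemble_candidates("visual", fm$data, fm$rad)), 9)
  # BAT-containing sets exclude onset time
  rb <- assemble_candidates("radiomics_bat", fm$data, fm$rad)
  expect_false("onset_to_ct" %in% colnames(rb))
  # select variants: 6 selected features + 5 clinical + onset
  sel <- paste0("rad", 1:3)
  src <- assemble_candidates("select_radiomics_clinical", fm$data, fm$rad,
                             select_features = sel)
  expect_equal(ncol(src), 3 + 5 + 1)
  expect_error(assemble_candidates("select_radiomics_clinical", fm$data,
                                   fm$rad), "select_features")
  expect_error(assemble_candidates("nope", fm$data, fm$rad), "valid names")
})

test_that("forced maximal penalty yields an intercept-only signature", {
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- rbinom(200, 1, 0.3)
  sig <- fit_signature(X, y, seed = 1)
  # emulate lambda -> Inf by scoring with an intercept-only signature
  s0 <- sig; s0$variables <- character(0); s0$weights <- numeric(0)
  sc <- score_signature(s0, tibble::as_tibble(as.data.frame(X)))
  expect_equal(length(unique(sc)), 1L)
})

test_that("planted predictors are recovered among noise columns", {
  hits <- 0; total <- 25
  for (s in seq_len(total)) {
    set.seed(1000 + s)
    n <- 600
    X <- matrix(rnorm(n * 50), n, 50,
                dimnames = list(NULL, paste0("v", 1:50)))
    eta <- X[, 1] - X[, 2] - 1
    y <- rbinom(n, 1, plogis(eta))
    sig <- fit_signature(X, y, seed = s)
    if (all(c("v1", "v2") %in% sig$variables)) hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})

test_that("a duplicated informative column splits weight stably", {
  set.seed(5)
  n <- 800
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x - 1))
  X1 <- cbind(x = x, n1 = rnorm(n))
  X2 <- cbind(x = x, x_dup = x, n1 = X1[, "n1"])
  s1 <- fit_signature(X1, y, seed = 3)
  s2 <- fit_signature(X2, y, seed = 3)
  w1 <- sum(s1$weights[names(s1$weights) %in% "x"])
  w2 <- sum(s2$weights[names(s2$weights) %in% c("x", "x_dup")])
  expect_lt(abs(w2 - w1) / abs(w1), 0.10)
})

test_that("signature scores are linear with the stored weights", {
  fm <- fake_model_data(n = 200, seed = 7)
  y <- rbinom(200, 1, plogis(fm$data$rad1))
  X <- assemble_candidates("radiomics", fm$data, fm$rad)
  sig <- fit_signature(X, y, seed = 2)
  sc <- score_signature(sig, fm$data)
  if (length(sig$variables)) {
    v <- sig$variables[1]
    d2 <- fm$data
    d2[[v]] <- d2[[v]] + 1
    expect_equal(score_signature(sig, d2) - sc,
                 rep(sig$weights[[v]], nrow(d2)), tolerance = 1e-12)
  }
  expect_error(score_signature(sig, fm$data[, -1]), "missing")
})

test_that("stored CV-fold AUCs replay from the prevalidated scores", {
  set.seed(11)
  n <- 300
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- rbinom(n, 1, plogis(X[, 1] - 1))
  sig <- fit_signature(X, y, seed = 4)
  expect_true(is.finite(sig$cv_auc_mean))
  expect_true(sig$cv_auc_se >= 0)
  expect_equal(length(sig$cv_fold_auc), sig$nfolds)
  # deterministic refit
  sig2 <- fit_signature(X, y, seed = 4)
  expect_identical(sig$weights, sig2$weights)
  expect_identical(sig$cv_fold_auc, sig2$cv_fold_auc)
})

test_that("single-class labels and tiny samples are rejected", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_signature(X, rep(1, 20)), "both")
  expect_error(fit_signature(X, rep(c(0, 1), c(15, 5)), nfolds = 10L), "fold")
})
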