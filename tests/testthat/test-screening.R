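test_that("ICC(2,1): perfect agreement, hand-computed toy, null noise", {
  perfect <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc21(perfect), 1)
  # 4 patients x 2 raters toy table, hand ANOVA
  toy <- cbind(c(9, 6, 8, 7), c(2, 1, 4, 1))
  n <- 4; k <- 2
  gm <- mean(toy)
  msr <- k * sum((rowMeans(toy) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(toy) - gm)^2) / (k - 1)
  mse <- (sum((toy - gm)^2) - k * sum((rowMeans(toy) - gm)^2) -
            n * sum((colMeans(toy) - gm)^2)) / ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc21(toy), icc_hand, tolerance = 1e-10)
  # pure noise: ICC near 0
  set.seed(8)
  noise <- matrix(rnorm(300), 100, 3)
  expect_lt(abs(icc21(noise)), 0.1)
  # zero variance: undefined
  expect_true(is.nan(icc21(matrix(5, 4, 2))))
  expect_error(icc21(matrix(1, 1, 2)), "2 patients")
})

make_rep_tables <- function(n = 40, seed = 1) {
  set.seed(seed)
  base <- tibble::tibble(patient_id = 1:n,
                         stable = rnorm(n, 50, 10),
                         noisy = rnorm(n))
  reps <- lapply(1:3, function(r) {
    t <- base
    t$stable <- t$stable + rnorm(n, 0, 0.1) # tiny replicate jitter
    t$noisy <- rnorm(n)                     # no patient component at all
    t
  })
  reps
}

test_that("stability filter keeps stable features and removes noise", {
  reps <- make_rep_tables()
  st <- stability_filter(reps, icc_threshold = 0.9)
  expect_true("stable" %in% st$retained)
  expect_false("noisy" %in% st$retained)
  # a permissive threshold retains every feature with a defined ICC
  st0 <- stability_filter(reps, icc_threshold = -1)
  expect_setequal(st0$retained, c("stable", "noisy"))
  # retained set shrinks as the threshold tightens
  expect_true(all(st$retained %in% st0$retained))
})

test_that("collinearity filter: duplicates, perfect triples, independent noise", {
  set.seed(2)
  n <- 120
  a <- rnorm(n)
  tbl <- tibble::tibble(patient_id = 1:n, f_a = a, f_dup = a,
                        f_b = rnorm(n), f_c = rnorm(n))
  out <- collinearity_filter(tbl, 0.8)
  expect_equal(sum(c("f_a", "f_dup") %in% out$retained), 1)
  expect_true(all(c("f_b", "f_c") %in% out$retained))
  # three exactly collinear features: exactly one kept
  tbl3 <- tibble::tibble(patient_id = 1:n, g1 = a, g2 = 2 * a, g3 = -a + 5)
  out3 <- collinearity_filter(tbl3, 0.8)
  expect_length(out3$retained, 1)
  # independent noise at generous n: everything survives
  set.seed(3)
  big <- tibble::as_tibble(as.data.frame(matrix(rnorm(500 * 12), 500, 12)))
  big$patient_id <- 1:500
  expect_length(collinearity_filter(big, 0.8)$retained, 12)
  # constant feature dropped up front
  tblc <- tibble::tibble(patient_id = 1:n, h1 = a, h2 = rep(1, n))
  expect_false("h2" %in% suppressMessages(collinearity_filter(tblc, 0.8))$retained)
})

test_that("screening report nests the retained sets", {
  reps <- make_rep_tables()
  primary <- reps[[1]]
  rep_scr <- screen_features(primary, reps, icc_threshold = 0.9,
                             r_threshold = 0.8)
  expect_true(all(rep_scr$retained_collinearity %in%
                    rep_scr$retained_stability))
  expect_equal(rep_scr$n_input, 2)
})

test_that("standardization uses discovery statistics everywhere", {
  set.seed(6)
  disc <- tibble::tibble(x = rnorm(50, 10, 3), b = rbinom(50, 1, 0.4))
  vali <- tibble::tibble(x = rnorm(50, 14, 3), b = rbinom(50, 1, 0.4))
  par <- fit_standardization(disc)
  d2 <- standardize_apply(disc, par)
  expect_equal(mean(d2$x), 0, tolerance = 1e-12)
  expect_equal(sd(d2$x), 1, tolerance = 1e-12)
  v2 <- standardize_apply(vali, par)
  expect_equal(v2$x, (vali$x - mean(disc$x)) / sd(disc$x))
  expect_gt(abs(mean(v2$x)), 0.5) # validation mean shifted, not re-centred
  # binary column passes through unchanged
  expect_identical(v2$b, vali$b)
  expect_error(standardize_apply(vali["b"], par), "missing")
})

test_that("median imputation uses discovery medians", {
  disc <- tibble::tibble(v = c(1, 2, NA, 4))
  par <- fit_imputation(disc, "v")
  expect_equal(par$medians[["v"]], 2)
  vali <- tibble::tibble(v = c(NA, 7))
  out <- impute_apply(vali, par)
  expect_equal(out$v, c(2, 7))
  expect_equal(attr(out, "n_imputed"), 1L)
  # no missing values: unchanged
  full <- tibble::tibble(v = c(5, 6))
  expect_equal(impute_apply(full, par)$v, c(5, 6))
  expect_error(fit_imputation(tibble::tibble(v = c(NA_real_, NA_real_)), "v"),
               "all values missing")
})

test_that("fitted screening parameters ignore validation rows (anti-leakage)", {
  set.seed(7)
  disc <- tibble::tibble(patient_id = 1:60,
                         f1 = rnorm(60), f2 = rnorm(60))
  vali1 <- tibble::tibble(patient_id = 61:120, f1 = rnorm(60), f2 = rnorm(60))
  vali2 <- vali1
  vali2$f1 <- vali2$f1 * 10 + 100 # aggressive perturbation
  p1 <- fit_standardization(disc)
  expect_identical(fit_standardization(disc), p1)
  # perturbing validation cannot reach into fit-on-discovery objects by
  # construction; applying them to different validation data changes only
  # the outputs, not the parameters
  s1 <- standardize_apply(vali1, p1)
  s2 <- standardize_apply(vali2, p1)
  expect_identical(p1$mean, fit_standardization(disc)$mean)
  expect_false(identical(s1$f1, s2$f1))
})
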