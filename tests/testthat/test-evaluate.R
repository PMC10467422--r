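test_that("AUC equals exhaustive pair counting (ties = 1/2)", {
  set.seed(1)
  scores <- c(rnorm(5, 1), rnorm(5))
  labels <- rep(c(1, 0), each = 5)
  got <- auc_delong(scores, labels)
  expect_equal(got$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  # with ties
  s2 <- c(1, 2, 2, 3, 2, 2, 4, 1)
  l2 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(auc_delong(s2, l2)$auc, oracle_auc(s2, l2), tolerance = 1e-12)
  # perfect separation
  ps <- auc_delong(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(ps$auc, 1)
  expect_equal(ps$variance, 0)
  expect_error(auc_delong(1:4, rep(1, 4)), "class")
})

test_that("null AUC concentrates near 1/2 with a covering CI", {
  set.seed(2)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.3)
  a <- auc_delong(scores, labels)
  expect_lt(abs(a$auc - 0.5), 0.03)
  expect_true(a$ci[1] <= 0.5 && a$ci[2] >= 0.5)
})

test_that("paired DeLong test: identity, symmetry, permutation cross-check", {
  set.seed(3)
  labels <- rep(c(1, 0), times = c(8, 10))
  a <- rnorm(18)
  expect_equal(delong_test(a, a, labels)$p_value, 1)
  b <- rnorm(18)
  expect_equal(delong_test(a, b, labels)$p_value,
               delong_test(b, a, labels)$p_value)
  # toy-sized check against a permutation test of the AUC difference:
  # swap the two scores patient-wise with probability 1/2 (sign flip of the
  # paired difference under H0: equal AUCs)
  set.seed(4)
  labs <- rep(c(1, 0), times = c(6, 8))
  sa <- rnorm(14); sb <- rnorm(14) + 0.8 * sa
  obs <- abs(oracle_auc(sa, labs) - oracle_auc(sb, labs))
  B <- 4000
  cnt <- 0
  for (i in seq_len(B)) {
    swap <- runif(14) < 0.5
    pa <- ifelse(swap, sb, sa); pb <- ifelse(swap, sa, sb)
    if (abs(oracle_auc(pa, labs) - oracle_auc(pb, labs)) >= obs - 1e-12) {
      cnt <- cnt + 1
    }
  }
  p_perm <- cnt / B
  p_delong <- delong_test(sa, sb, labs)$p_value
  expect_lt(abs(p_delong - p_perm), 0.12) # Monte-Carlo + asymptotic slack
})

test_that("pROC agrees with our DeLong machinery", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(120); labels <- rbinom(120, 1, 0.4)
  ours <- auc_delong(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- suppressWarnings(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, as.numeric(ci)[c(1, 3)], tolerance = 1e-9)
  scores2 <- rnorm(120)
  ref2 <- pROC::roc(labels, scores2, quiet = TRUE, direction = "<")
  pr <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(delong_test(scores, scores2, labels)$p_value,
               as.numeric(pr$p.value), tolerance = 1e-9)
})

test_that("threshold metrics reuse the discovery cutoff on evaluation data", {
  # hand-built 10-patient table
  sd_ <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  ld <- c(1, 1, 0, 1, 1, 0, 0, 1, 0, 0)
  # recall >= 0.8 needs >= 4/5 positives at or above the cutoff; the largest
  # qualifying cutoff is 0.5 (at 0.6 only 3/5 positives remain)
  tm <- threshold_metrics(sd_, ld, sd_, ld, recall_floor = 0.8)
  expect_equal(tm$threshold, 0.5)
  pred <- sd_ >= 0.5
  expect_equal(tm$recall, sum(pred & ld == 1) / sum(ld == 1))
  expect_equal(tm$precision, sum(pred & ld == 1) / sum(pred))
  expect_equal(tm$npv, sum(!pred & ld == 0) / sum(!pred))
  expect_equal(tm$f1, 2 * tm$precision * tm$recall / (tm$precision + tm$recall))
  # perfect separation: all metrics 1
  sp <- c(5, 6, 7, 1, 2, 3); lp <- c(1, 1, 1, 0, 0, 0)
  tmp <- threshold_metrics(sp, lp, sp, lp)
  expect_equal(unlist(tmp[c("precision", "recall", "npv", "f1")]),
               c(precision = 1, recall = 1, npv = 1, f1 = 1))
  # all predicted positive: recall 1, precision = prevalence, NPV -> 1
  sall <- rep(1, 8); lall <- c(1, 1, 0, 0, 0, 0, 0, 0)
  tma <- threshold_metrics(sall, lall, sall, lall)
  expect_equal(tma$recall, 1)
  expect_equal(tma$precision, 0.25)
  expect_equal(tma$npv, 1)
  expect_error(threshold_metrics(sd_, ld, sd_, ld, recall_floor = 1.2),
               "recall_floor")
})

test_that("Spearman association: monotone, hand table with ties, null", {
  s <- c(0.1, 0.4, 0.5, 0.9)
  expect_equal(spearman_outcome(s, c(0, 2, 3, 6))$rho, 1)
  # 6-pair hand table with one tie, midrank convention
  sc <- c(1, 2, 3, 4, 5, 6)
  mr <- c(0, 1, 1, 3, 4, 6)
  rho_hand <- cor(rank(sc), rank(mr))
  got <- spearman_outcome(sc, mr)
  expect_equal(got$rho, rho_hand, tolerance = 1e-12)
  tstat <- rho_hand * sqrt((6 - 2) / (1 - rho_hand^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
  expect_equal(got$ci, tanh(atanh(rho_hand) + qnorm(0.975) * c(-1, 1) *
                              sqrt(1.06 / 3)), tolerance = 1e-12)
  # missing mRS rows are excluded and counted
  got2 <- spearman_outcome(c(sc, 7), c(mr, NA))
  expect_equal(got2$n_excluded, 1)
  expect_equal(got2$rho, got$rho)
  # null: rho near zero at n = 1000
  set.seed(6)
  nn <- spearman_outcome(rnorm(1000), sample(0:6, 1000, replace = TRUE))
  expect_lt(abs(nn$rho), 0.07)
  expect_error(spearman_outcome(1:3, c(1, 2, 3)), "4 patients")
})
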