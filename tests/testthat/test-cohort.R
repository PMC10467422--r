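spec_small <- compact_cohort_spec(n_patients = 10L)

test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(he_prevalence = 0), "he_prevalence")
  expect_error(cohort_spec(he_prevalence = 1), "he_prevalence")
  expect_error(cohort_spec(auc_target = 0.4), "auc_target")
})

test_that("lesion generation is a pure function of (spec, index, seed)", {
  a <- generate_lesion(spec_small, 3, 17)
  b <- generate_lesion(spec_small, 3, 17)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$latents, b$latents)
  c <- generate_lesion(spec_small, 4, 17)
  expect_false(identical(a$mask$voxels, c$mask$voxels))
})

test_that("zero heterogeneity gives an exactly constant lesion interior", {
  sp <- compact_cohort_spec(n_patients = 4L, het_sdlog = 1e-9,
                            het_meanlog = -30)
  les <- generate_lesion(sp, 1, 5)
  inside <- les$volume$voxels[les$mask$voxels == 1L]
  expect_lt(diff(range(inside)), 1e-6)
  expect_equal(mean(inside), les$latents$mean_hu, tolerance = 1e-6)
})

test_that("near-spherical lesion mask volume matches the analytic ball", {
  # irregularity ~ 0 and isotropic-ish axes: volume within 5% of measured
  sp <- cohort_spec(n_patients = 4L, irregularity_shape1 = 1e-3,
                    irregularity_shape2 = 1e3, in_plane_spacing = 1,
                    slice_thickness_levels = 1, slice_thickness_weights = 1,
                    volume_mean_cm3 = 4.2, volume_sd_cm3 = 0.01)
  les <- generate_lesion(sp, 2, 9)
  measured <- les$latents$volume_cm3
  expect_lt(abs(measured - 4.2) / 4.2, 0.06)
  # invariant: reported volume equals voxel count x voxel volume
  expect_equal(measured, mask_volume_cm3(les$mask))
})

test_that("lesion exceeding a fixed grid errors with the required size", {
  sp <- cohort_spec(n_patients = 4L, grid_dims = c(16, 16, 8),
                    volume_mean_cm3 = 30, volume_sd_cm3 = 0.1)
  expect_error(generate_lesion(sp, 1, 2), "need at least")
})

test_that("repeat masks: identity at zero jitter, high Dice at 1 mm, monotone decay", {
  m <- lesion_mask(make_ball(10))
  r0 <- generate_repeat_masks(m, 2, 0, seed = 3)
  expect_identical(r0[[1]]$voxels, m$voxels)
  expect_equal(dice_coefficient(m, r0[[2]]), 1)
  d1 <- mean(vapply(generate_repeat_masks(m, 4, 1, seed = 3),
                    dice_coefficient, numeric(1), a = m))
  expect_gt(d1, 0.85)
  dbig <- mean(vapply(generate_repeat_masks(m, 4, 10, seed = 3),
                      dice_coefficient, numeric(1), a = m))
  expect_lt(dbig, d1)
  expect_error(generate_repeat_masks(lesion_mask(array(0L, c(3, 3, 3))), 2, 1),
               "empty")
})

test_that("cohort allocation splits into equal disjoint halves", {
  p897 <- tibble::tibble(patient_id = 1:897)
  out <- allocate_cohorts(p897, seed = 5)
  expect_equal(sort(as.numeric(table(out$cohort))), c(448, 449))
  p4 <- allocate_cohorts(tibble::tibble(patient_id = 1:4), seed = 5)
  expect_equal(as.numeric(table(p4$cohort)), c(2, 2))
  expect_identical(allocate_cohorts(p897, seed = 9)$cohort,
                   allocate_cohorts(p897, seed = 9)$cohort)
  expect_error(allocate_cohorts(tibble::tibble(patient_id = 1), 1), "2")
})

test_that("tabular generation hits prevalence, marginals and label consistency", {
  sp <- compact_cohort_spec(n_patients = 2000L)
  set.seed(1)
  lat <- tibble::as_tibble(draw_latents_for_test(sp, 2000))
  tab <- generate_tabular(sp, lat, seed = 21)
  expect_lt(abs(mean(tab$he) - 0.27), 0.03)
  # label consistency: the volume rule reproduces every drawn label
  expect_equal(label_he(tab$baseline_volume, tab$followup_volume), tab$he)
  # clinical marginals within 3 SE
  expect_lt(abs(mean(tab$glucose) - 140.4), 3 * 59.8 / sqrt(2000))
  expect_lt(abs(mean(tab$platelets) - 223.0), 3 * 62.3 / sqrt(2000))
  expect_lt(abs(mean(tab$onset_to_ct) - 98.1), 3 * 49.6 / sqrt(2000))
  expect_lt(abs(sd(tab$glucose) - 59.8), 3 * 59.8 / sqrt(2 * 2000) + 2)
  expect_lt(abs(mean(tab$sex_male) - 0.592), 3 * sqrt(0.592 * 0.408 / 2000))
  # marker prevalences calibrated to the marginals
  expect_lt(abs(mean(tab$hypodensity) - 0.755), 0.04)
  expect_lt(abs(mean(tab$blend) - 0.087), 0.03)
  # mRS missing fraction and ordinal range
  expect_lt(abs(mean(is.na(tab$mrs)) - 0.029), 0.02)
  expect_true(all(tab$mrs[!is.na(tab$mrs)] %in% 0:6))
  # BAT-relevant fields behave
  expect_true(all(tab$onset_to_ct > 0))
})

test_that("planted-signal dial: true log-odds score attains the target AUC", {
  sp <- compact_cohort_spec(n_patients = 2000L)
  set.seed(2)
  lat <- tibble::as_tibble(draw_latents_for_test(sp, 10000))
  tab <- generate_tabular(sp, lat, seed = 3)
  auc <- oracle_auc_fast(tab$true_logodds, tab$he)
  expect_lt(abs(auc - 0.65), 0.02)
})

test_that("all-zero planted effects give a null association", {
  sp <- compact_cohort_spec(n_patients = 2000L,
                            planted_feature_effects = c(log_volume = 0,
                                                        mean_hu = 0,
                                                        heterogeneity = 0,
                                                        irregularity = 0))
  set.seed(3)
  lat <- tibble::as_tibble(draw_latents_for_test(sp, 2000))
  tab <- generate_tabular(sp, lat, seed = 4)
  auc <- oracle_auc_fast(scale(lat$log_volume), tab$he)
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("mRS is positively loaded on HE", {
  sp <- compact_cohort_spec(n_patients = 2000L)
  set.seed(4)
  lat <- tibble::as_tibble(draw_latents_for_test(sp, 2000))
  tab <- generate_tabular(sp, lat, seed = 5)
  keep <- !is.na(tab$mrs)
  expect_gt(mean(tab$mrs[keep & tab$he == 1]), mean(tab$mrs[keep & tab$he == 0]))
})

test_that("missing latent columns are reported by name", {
  lat <- tibble::tibble(log_volume = 1, mean_hu = 60)
  expect_error(generate_tabular(spec_small, lat, 1), "heterogeneity")
})
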