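# Synthetic cohort generator: determinism, clinical-grid correctness,
# class structure, calibration helpers, reference and training cohorts.

test_that("identical config and seed give identical cohorts; seeds change them", {
  cfg <- small_config()
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$participants, b$participants)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$provenance$tag, b$provenance$tag)
  c <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$profiles, c$profiles))
  expect_false(identical(a$provenance$tag, c$provenance$tag))
})

test_that("reference-scale cohort has the expected class structure", {
  co <- generate_cohort(sim_config(), seed = 3)
  pt <- co$participants
  expect_equal(nrow(pt), 160)
  expect_equal(sum(pt$diagnosis %in% c("RRMS", "ProgMS")), 96)
  expect_equal(sum(pt$diagnosis %in% c("OIND", "NIND")), 64)
  expect_equal(as.vector(table(pt$diagnosis)), c(65, 31, 30, 34))
  expect_false(anyDuplicated(pt$participant_id) > 0)
  expect_setequal(pt$participant_id, co$profiles$participant_id)
  # controls are not followed: EDSS timeline entirely missing
  ctrl <- pt$diagnosis %in% c("OIND", "NIND")
  expect_true(all(is.na(pt$baseline_edss[ctrl])))
  expect_true(all(is.na(pt$followup_edss[ctrl])))
  expect_true(all(is.na(pt$interval_years[ctrl])))
  # abundances strictly positive (log-transformable)
  expect_true(all(as.matrix(co$profiles[, -1]) > 0))
})

test_that("measured EDSS lies on the clinical half-point grid", {
  grid <- c(0, seq(1, 10, by = 0.5))
  for (s in 1:5) {
    pt <- generate_cohort(small_config(), seed = s)$participants
    obs <- c(pt$baseline_edss, pt$followup_edss)
    expect_true(all(obs[!is.na(obs)] %in% grid))
  }
  # grid rounding: no half-point below 1.0, half-up at midpoints
  expect_equal(edss_grid_round(c(0.2, 0.49, 0.5, 0.9, 1.24, 1.25, 3.33, 10.7)),
               c(0, 0, 1, 1, 1, 1.5, 3.5, 10))
})

test_that("analytic_auc matches a Monte-Carlo oracle and basic limits", {
  expect_equal(analytic_auc(0), 0.5)
  expect_gt(analytic_auc(20), 1 - 1e-9)  # effect -> Inf limit
  set.seed(401)
  x <- rnorm(1e6, mean = 2); y <- rnorm(1e6)
  expect_equal(analytic_auc(2), mean(x > y), tolerance = 0.002)
  expect_equal(effect_for_auc(analytic_auc(1.3)), 1.3, tolerance = 1e-12)
  expect_error(analytic_auc(Inf), "finite")
})

test_that("null effects give AUROC near 0.5 and calibrated effects near target", {
  null_cfg <- small_config(diag_effect = 0, prog_effect = 0)
  aucs <- vapply(1:50, function(s) {
    co <- generate_cohort(null_cfg, seed = s)
    ms <- co$participants$diagnosis %in% c("RRMS", "ProgMS")
    auroc(co$provenance$truth$diag_factor, ms)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  cal_cfg <- sim_config(diag_effect = effect_for_auc(0.94))
  cal <- vapply(1:50, function(s) {
    co <- generate_cohort(cal_cfg, seed = s)
    ms <- co$participants$diagnosis %in% c("RRMS", "ProgMS")
    auroc(co$provenance$truth$diag_factor, ms)$auc
  }, numeric(1))
  expect_lt(abs(mean(cal) - 0.94), 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(interval_mean_years = -1), "interval_mean_years")
  expect_error(sim_config(n_rrms = -2), "counts")
  expect_error(generate_cohort(sim_config(n_rrms = 0, n_progms = 0,
                                          n_oind = 0, n_nind = 0)),
               "empty cohort")
  expect_error(generate_healthy_reference(10, config = small_config()),
               ">= 20")
})

test_that("healthy reference carries only age/sex structure, recoverable by OLS", {
  cfg <- small_config(age_slope_per_protein = 0.01,
                      sex_offset_per_protein = 0, noise_sd = 0.1)
  ref <- generate_healthy_reference(200, config = cfg, seed = 5)
  expect_true(all(ref$participants$diagnosis == "Healthy"))
  fit <- fit_healthy_reference(ref)
  # recovered age slopes within 20% of the generating 0.01/yr
  expect_lt(abs(median(fit$coefficients$age_slope) - 0.01), 0.002)

  # null effects: fitted slopes consistent with zero for nearly all proteins
  cfg0 <- small_config(age_slope_per_protein = 0, sex_offset_per_protein = 0)
  fit0 <- fit_healthy_reference(generate_healthy_reference(100, config = cfg0,
                                                           seed = 6))
  pt0 <- generate_healthy_reference(100, config = cfg0, seed = 6)$participants
  se_scale <- fit0$coefficients$residual_sd / (sd(pt0$age_at_lp) * sqrt(100))
  expect_gt(mean(abs(fit0$coefficients$age_slope) < 3 * se_scale), 0.95)
})

test_that("training cohort exposes severity targets with recoverable structure", {
  cfg <- sim_config(n_rrms = 200, n_progms = 100, n_noise_proteins = 20,
                    slope_a = 0.2, slope_b = 0.5, slope_sd = 0.05,
                    nonprogressor_floor_frac = 0)
  tc <- generate_training_cohort(cfg, seed = 8)
  pt <- tc$participants
  expect_true(all(pt$diagnosis %in% c("RRMS", "ProgMS")))
  expect_true(all(c("msdss_true", "combiwise_slope_true") %in% names(pt)))
  expect_equal(tc$provenance$truth_params$slope_a, 0.2)
  # severity score is monotone in latent severity
  expect_equal(cor(pt$msdss_true, pt$latent_severity), 1)
  # OLS on the generated table recovers (a, b) within 10%
  fit <- fit_msdss_slope_model(pt$msdss_true, pt$combiwise_slope_true)
  expect_lt(abs(fit$a - 0.2) / 0.2, 0.1)
  expect_lt(abs(fit$b - 0.5) / 0.5, 0.1)
  # b_true = 0: fitted slope within 3 SE of zero
  cfg0 <- sim_config(n_rrms = 200, n_progms = 100, n_noise_proteins = 20,
                     slope_b = 0, nonprogressor_floor_frac = 0)
  tc0 <- generate_training_cohort(cfg0, seed = 9)
  fit0 <- fit_msdss_slope_model(tc0$participants$msdss_true,
                                tc0$participants$combiwise_slope_true)
  expect_lt(abs(fit0$b), 3 * fit0$se[2])
})

test_that("cohorts round-trip through the CSV writer", {
  co <- generate_cohort(small_config(), seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.json")))
  back <- read_cohort(dir)
  expect_equal(back$participants$participant_id, co$participants$participant_id)
  expect_equal(back$participants$baseline_edss, co$participants$baseline_edss)
  expect_equal(as.matrix(back$profiles[, -1]), as.matrix(co$profiles[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_match(back$provenance$tag, "^file-")
})
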