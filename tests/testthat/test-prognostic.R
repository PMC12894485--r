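# Prognostic chain: conversion fits, quadratic inversion, follow-up EDSS
# propagation, explained-variance gain, multivariate model, MRI baseline.

test_that("slope model recovers a noise-free line exactly and validates input", {
  msdss <- seq(1, 8, length.out = 20)
  fit <- suppressWarnings(fit_msdss_slope_model(msdss, 0.2 + 0.5 * msdss))
  expect_equal(fit$a, 0.2, tolerance = 1e-12)
  expect_equal(fit$b, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_msdss_slope_model(msdss[1:5], msdss[1:5]), "n >= 10")
  expect_error(fit_msdss_slope_model(rep(3, 20), rnorm(20)), "constant")
})

test_that("quadratic conversion fit recovers known coefficients and its domain", {
  cw <- seq(0, 90, length.out = 50)
  edss <- 0.2 + 0.06 * cw + 0.0004 * cw^2
  fit <- suppressWarnings(fit_combiwise_edss_model(cw, edss))
  expect_equal(c(fit$c0, fit$c1, fit$c2), c(0.2, 0.06, 0.0004),
               tolerance = 1e-8)
  expect_equal(fit$domain, c(0, 100))
  # pure linear generator: fitted curvature within 3 SE of zero
  set.seed(201)
  edss_lin <- 0.1 * cw + rnorm(50, 0, 0.3)
  fit_lin <- fit_combiwise_edss_model(cw, edss_lin)
  se_c2 <- summary(lm(edss_lin ~ cw + I(cw^2)))$coefficients[3, 2]
  expect_lt(abs(fit_lin$c2), 3 * se_c2)
  narrow <- seq(0, 25, length.out = 25)
  expect_error(suppressWarnings(fit_combiwise_edss_model(narrow, 0.1 * narrow)),
               "span")
  expect_error(fit_combiwise_edss_model(cw[1:10], edss[1:10]), "n >= 20")
  dec <- 5 - 0.06 * cw + 0.0001 * cw^2 + rnorm(50, 0, 0.05)
  expect_warning(fit_combiwise_edss_model(cw, dec),
                 "non-monotone|non-increasing")
})

test_that("cross-sectional simulation supports the conversion fit", {
  cfg <- sim_config()
  cross <- simulate_disability_crosssection(3000, cfg, seed = 7)
  fit <- fit_combiwise_edss_model(cross$combiwise, cross$edss)
  pred <- fit$c0 + fit$c1 * cross$combiwise + fit$c2 * cross$combiwise^2
  rmse <- sqrt(mean((pred - cross$edss)^2))
  expect_lte(rmse, 2 * cfg$edss_noise_sd)
})

test_that("quadratic inversion is exact on the monotone domain", {
  cm <- known_conversion(c0 = 0, c1 = 0.1, c2 = 0)
  expect_equal(edss_to_combiwise(2.0, cm), 20.0)   # linear special case
  set.seed(202)
  worst <- 0
  for (i in 1:100) {
    c2 <- runif(1, 1e-5, 9e-4); c1 <- runif(1, 0.02, 0.1); c0 <- runif(1, -0.5, 0.5)
    cmi <- known_conversion(c0 = c0, c1 = c1, c2 = c2)
    e <- runif(100, c0 + 1e-3, c0 + c1 * 100 + c2 * 1e4 - 1e-3)
    cw <- edss_to_combiwise(e, cmi)
    back <- cmi$edss$c0 + cmi$edss$c1 * cw + cmi$edss$c2 * cw^2
    worst <- max(worst, max(abs(back - e)))
  }
  expect_lt(worst, 1e-9)
  # out-of-range EDSS clamps to the domain endpoint with a warning
  expect_warning(lo <- edss_to_combiwise(-1, cm), "below")
  expect_equal(lo, 0)
  expect_warning(hi <- edss_to_combiwise(11, cm), "above")
  expect_equal(hi, 100)
})

test_that("chain identity and monotonicity hold", {
  cm <- known_conversion(a = 0.5, b = 0.1)
  # interval 0: predicted equals baseline exactly
  pr0 <- predict_followup_edss(c(2, 5, 8), c(1, 3.5, 6), c(0, 0, 0), cm)
  expect_identical(pr0$predicted_followup_edss, c(1, 3.5, 6))
  expect_identical(pr0$delta_edss, c(0, 0, 0))
  # b = 0: identical delta_cw regardless of severity
  cm0 <- known_conversion(a = 0.8, b = 0)
  prb <- predict_followup_edss(c(1, 4, 9), rep(3, 3), rep(5, 3), cm0)
  expect_equal(prb$delta_cw, rep(4, 3))
  # monotone in severity and in interval (b > 0)
  pr_sev <- predict_followup_edss(seq(0, 9, 0.5), rep(3, 19), rep(6, 19), cm)
  expect_true(all(diff(pr_sev$predicted_followup_edss) >= 0))
  pr_int <- predict_followup_edss(rep(5, 16), rep(3, 16), seq(0, 30, 2), cm)
  expect_true(all(diff(pr_int$predicted_followup_edss) >= 0))
  expect_true(all(pr_int$predicted_followup_edss <= 10))
  # missing inputs are skipped with reasons
  prm <- predict_followup_edss(c(5, NA, 5), c(3, 3, NA), c(4, 4, 4), cm)
  expect_equal(nrow(prm), 1)
  skipped <- attr(prm, "skipped")
  expect_setequal(skipped$reason,
                  c("missing severity prediction", "missing baseline EDSS"))
  expect_error(predict_followup_edss(5, 3, -1, cm), ">= 0")
})

test_that("negative slopes are allowed and the EDSS floor clamps at 0", {
  cm <- known_conversion(a = -2, b = 0)
  pr <- suppressWarnings(
    predict_followup_edss(rep(1, 3), c(0.5, 1, 2), rep(10, 3), cm))
  expect_true(all(pr$delta_edss <= 0))
  expect_true(all(pr$predicted_followup_edss >= 0))
})

test_that("prognosis evaluation reports rho, nested R2 and the gain test", {
  cm <- known_conversion(a = 0.5, b = 0.15)
  set.seed(203)
  n <- 60
  base <- runif(n, 1, 6); sev <- rnorm(n, 4, 1.2); int <- runif(n, 4, 14)
  pr <- predict_followup_edss(sev, base, int, cm)
  measured <- pr$predicted_followup_edss + rnorm(n, 0, 0.4)
  ev <- evaluate_prognosis(pr, measured)
  expect_gt(ev$spearman_rho, 0.8)
  expect_gte(ev$r2_augmented, ev$r2_base)
  expect_lt(ev$p_gain, 0.01)
  # exact predictions: rho = 1, augmented R2 = 1
  exact <- suppressWarnings(evaluate_prognosis(pr, pr$predicted_followup_edss))
  expect_equal(exact$spearman_rho, 1)
  expect_equal(exact$r2_augmented, 1, tolerance = 1e-9)
  # all-zero predicted change: R2 gain collapses, gain p missing
  pr0 <- predict_followup_edss(sev, base, rep(0, n), cm)
  ev0 <- evaluate_prognosis(pr0, measured)
  expect_equal(ev0$r2_augmented, ev0$r2_base)
  expect_true(is.na(ev0$p_gain))
  expect_error(evaluate_prognosis(pr[1:5, ], measured[1:5]), ">= 10")
})

test_that("explained-variance gain is positive and often significant at study scale", {
  cfg <- sim_config(n_rrms = 60, n_progms = 29)
  cm <- known_conversion(a = cfg$slope_a, b = cfg$slope_b,
                         c0 = cfg$cw_coef[1], c1 = cfg$cw_coef[2],
                         c2 = cfg$cw_coef[3])
  res <- vapply(1:30, function(s) {
    co <- generate_cohort(cfg, seed = s)
    pt <- co$participants; tr <- co$provenance$truth
    ms <- pt$diagnosis %in% c("RRMS", "ProgMS")
    pr <- suppressWarnings(
      predict_followup_edss(tr$msdss_true[ms], pt$baseline_edss[ms],
                            pt$interval_years[ms], cm,
                            participant_id = pt$participant_id[ms]))
    meas <- pt$followup_edss[ms][match(pr$participant_id, pt$participant_id[ms])]
    ev <- evaluate_prognosis(pr, meas)
    c(gain = ev$r2_augmented - ev$r2_base, p = ev$p_gain)
  }, numeric(2))
  expect_gt(mean(res["gain", ]), 0.02)      # positive mean gain
  expect_gt(mean(res["p", ] < 0.05), 0.5)   # significant in a majority of seeds
})

test_that("multivariate follow-up model recovers planted coefficients", {
  # zero-noise exact recovery
  set.seed(204)
  n <- 96
  base <- runif(n, 0, 6); age <- runif(n, 20, 65); prob <- runif(n)
  y <- 1 + 0.33 * base + 0.04 * age + 2.9 * prob
  fit <- suppressWarnings(multivariate_followup_model(base, age, prob, y))
  expect_equal(unname(fit$coefficients[, "Estimate"]),
               c(1, 0.33, 0.04, 2.9), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # collinear design warns
  expect_warning(multivariate_followup_model(base, base * 2, prob,
                                             y + rnorm(n, 0, 0.1)),
                 "collinear")
  expect_error(multivariate_followup_model(base[1:5], age[1:5], prob[1:5],
                                           y[1:5]), ">= 10")
})

test_that("MRI baseline estimate is a clamped linear combination", {
  scores <- cbind(mri_s1 = c(0, 2, 30), mri_s2 = c(0, 1, 30),
                  mri_s3 = c(0, 0.5, 30))
  w0 <- list(intercept = 2, coefficients = c(mri_s1 = 0, mri_s2 = 0, mri_s3 = 0))
  expect_equal(mri_baseline_edss(scores, w0), rep(2, 3))
  w <- default_mri_weights()
  est <- mri_baseline_edss(scores, w)
  expect_equal(est[1], 0)
  expect_equal(est[3], 10)   # clamp at the EDSS ceiling
  expect_error(mri_baseline_edss(scores[, 1:2], w), "mri_s3")
  # generator's MRI estimate tracks true baseline disability within noise
  co <- generate_cohort(sim_config(), seed = 205)
  pt <- co$participants; tr <- co$provenance$truth
  ok <- !is.na(pt$mri_edss_estimate)
  expect_gt(cor(pt$mri_edss_estimate[ok], tr$baseline_edss_true[ok]), 0.7)
  resid <- pt$mri_edss_estimate[ok] - tr$baseline_edss_true[ok]
  expect_lt(sd(resid), 1.2)
})
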