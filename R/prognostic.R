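# The prognostic chain: CSF-predicted severity -> CombiWISE progression slope
# -> CombiWISE change over the follow-up interval -> EDSS change -> predicted
# follow-up EDSS.
#
# Because the predicted disability change is usually smaller than the
# minimally detectable half-point EDSS increment, intermediate arithmetic is
# done on the continuous 0-100 CombiWISE scale and converted back to EDSS
# through a fitted monotone quadratic. The change is computed as a difference
# of the forward map, delta_edss = q(cw_base + delta_cw) - q(cw_base), and
# added to the baseline; a pure linear conversion mode is available.

#' Fit the severity-to-slope conversion (linear part of the chain)
#'
#' OLS of the observed CombiWISE progression slope (units/year) on the
#' severity score.
#'
#' @param msdss numeric severity scores (>= 10, non-constant).
#' @param observed_slopes observed CombiWISE slopes, aligned.
#' @return object of class \code{msdss_slope_model}: list with \code{a}
#'   (intercept), \code{b} (slope), standard errors, \code{r_squared},
#'   \code{sigma}, \code{n}.
#' @export
fit_msdss_slope_model <- function(msdss, observed_slopes) {
  keep <- stats::complete.cases(msdss, observed_slopes)
  msdss <- msdss[keep]; observed_slopes <- observed_slopes[keep]
  if (length(msdss) < 10)
    stop_csf("slope model needs n >= 10 complete pairs (got %d)", length(msdss))
  if (stats::sd(msdss) == 0)
    stop_csf("degenerate design: severity scores are constant")
  fit <- stats::lm(observed_slopes ~ msdss)
  s <- summary(fit)
  structure(
    list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
         se = unname(s$coefficients[, "Std. Error"]),
         r_squared = s$r.squared, sigma = s$sigma, n = length(msdss)),
    class = "msdss_slope_model"
  )
}

#' Fit the CombiWISE-to-EDSS conversion (quadratic part of the chain)
#'
#' Least-squares quadratic of EDSS on the continuous disability scale,
#' together with the domain on which the fitted curve is strictly
#' increasing. A warning is raised when the curve is non-monotone inside the
#' observed range.
#'
#' @param cw CombiWISE values (0-100); must span at least 30 units, n >= 20.
#' @param edss aligned EDSS values.
#' @return object of class \code{combiwise_edss_model}: coefficients
#'   \code{c0}, \code{c1}, \code{c2}, monotone \code{domain} within [0, 100],
#'   linear fallback coefficients \code{lin0}, \code{lin1}, fit diagnostics.
#' @export
fit_combiwise_edss_model <- function(cw, edss) {
  keep <- stats::complete.cases(cw, edss)
  cw <- cw[keep]; edss <- edss[keep]
  if (length(cw) < 20) stop_csf("conversion fit needs n >= 20 (got %d)", length(cw))
  if (diff(range(cw)) < 30)
    stop_csf("insufficient span: CombiWISE values cover %.1f units (need >= 30)",
             diff(range(cw)))
  fit <- stats::lm(edss ~ cw + I(cw^2))
  cf <- unname(stats::coef(fit))
  c0 <- cf[1]; c1 <- cf[2]; c2 <- cf[3]
  if (abs(c2) < 1e-12) {
    domain <- if (c1 > 0) c(0, 100) else c(NA_real_, NA_real_)
    if (c1 <= 0) warn_csf("fitted conversion is non-increasing")
  } else {
    vertex <- -c1 / (2 * c2)
    domain <- if (c2 > 0) c(max(0, vertex), 100) else c(0, min(100, vertex))
  }
  if (!anyNA(domain) &&
      (min(cw) < domain[1] - 1e-9 || max(cw) > domain[2] + 1e-9)) {
    warn_csf("fitted quadratic is non-monotone inside the observed CombiWISE range [%.1f, %.1f]",
             min(cw), max(cw))
  }
  linfit <- stats::lm(edss ~ cw)
  s <- summary(fit)
  structure(
    list(c0 = c0, c1 = c1, c2 = c2, domain = domain,
         lin0 = unname(stats::coef(linfit)[1]),
         lin1 = unname(stats::coef(linfit)[2]),
         r_squared = s$r.squared, sigma = s$sigma, n = length(cw)),
    class = "combiwise_edss_model"
  )
}

#' Bundle the two conversion fits of the prognostic chain
#'
#' @param slope_model a [fit_msdss_slope_model()] object.
#' @param edss_model a [fit_combiwise_edss_model()] object.
#' @param mode \code{"quadratic"} (default): EDSS change is a difference of
#'   the quadratic forward map; \code{"linear"}: EDSS change is
#'   \code{lin1 * delta_cw}, independent of baseline position.
#' @return object of class \code{conversion_models}.
#' @export
conversion_models <- function(slope_model, edss_model,
                              mode = c("quadratic", "linear")) {
  stopifnot(inherits(slope_model, "msdss_slope_model"),
            inherits(edss_model, "combiwise_edss_model"))
  structure(list(slope = slope_model, edss = edss_model,
                 mode = match.arg(mode)),
            class = "conversion_models")
}

#' @export
print.conversion_models <- function(x, ...) {
  cat("Prognostic conversion models\n")
  cat(sprintf("  slope: cw/yr = %.4f + %.4f * severity (R2 %.2f, n %d)\n",
              x$slope$a, x$slope$b, x$slope$r_squared, x$slope$n))
  cat(sprintf("  edss(cw) = %.4g + %.4g cw + %.4g cw^2 on [%.1f, %.1f] (R2 %.2f, n %d)\n",
              x$edss$c0, x$edss$c1, x$edss$c2, x$edss$domain[1],
              x$edss$domain[2], x$edss$r_squared, x$edss$n))
  cat(sprintf("  conversion mode: %s\n", x$mode))
  invisible(x)
}

#' @export
coef.conversion_models <- function(object, ...) {
  c(a = object$slope$a, b = object$slope$b,
    c0 = object$edss$c0, c1 = object$edss$c1, c2 = object$edss$c2)
}

# Forward quadratic map on the monotone domain (cw clamped to domain).
cw_to_edss_fitted <- function(cw, em, warn = TRUE) {
  out_of <- cw < em$domain[1] - 1e-9 | cw > em$domain[2] + 1e-9
  if (warn && any(out_of, na.rm = TRUE))
    warn_csf("%d CombiWISE value(s) outside the monotone domain were clamped",
             sum(out_of, na.rm = TRUE))
  cwc <- clamp(cw, em$domain[1], em$domain[2])
  em$c0 + em$c1 * cwc + em$c2 * cwc^2
}

#' Invert the fitted CombiWISE-to-EDSS quadratic
#'
#' Unique root of \code{c2 x^2 + c1 x + (c0 - edss)} inside the monotone
#' domain. EDSS values outside the attainable range are clamped to the domain
#' endpoint with a warning.
#'
#' @param edss EDSS values to invert (vectorized).
#' @param models a [conversion_models()] object (or a
#'   \code{combiwise_edss_model}).
#' @return CombiWISE values in the monotone domain.
#' @export
edss_to_combiwise <- function(edss, models) {
  em <- if (inherits(models, "conversion_models")) models$edss else models
  stopifnot(inherits(em, "combiwise_edss_model"))
  lo <- em$domain[1]; hi <- em$domain[2]
  e_lo <- em$c0 + em$c1 * lo + em$c2 * lo^2
  e_hi <- em$c0 + em$c1 * hi + em$c2 * hi^2
  out <- vapply(edss, function(e) {
    if (is.na(e)) return(NA_real_)
    if (e < min(e_lo, e_hi) || e > max(e_lo, e_hi)) return(NA_real_)
    r <- quad_roots(em$c2, em$c1, em$c0 - e)
    r <- r[r >= lo - 1e-6 & r <= hi + 1e-6]
    if (!length(r)) NA_real_ else clamp(r[which.min(abs(r - (lo + hi) / 2))], lo, hi)
  }, numeric(1))
  below <- !is.na(edss) & edss < min(e_lo, e_hi)
  above <- !is.na(edss) & edss > max(e_lo, e_hi)
  if (any(below)) {
    warn_csf("%d EDSS value(s) below the attainable range; clamped to the domain endpoint",
             sum(below))
    out[below] <- if (e_lo < e_hi) lo else hi
  }
  if (any(above)) {
    warn_csf("%d EDSS value(s) above the attainable range; clamped to the domain endpoint",
             sum(above))
    out[above] <- if (e_lo < e_hi) hi else lo
  }
  out
}

#' Propagate CSF-predicted severity to a predicted follow-up EDSS
#'
#' For each participant: slope_cw = a + b * severity; delta_cw = slope_cw *
#' interval; the baseline EDSS is mapped to the CombiWISE scale, shifted by
#' delta_cw (clamped to the monotone domain), mapped back, and the resulting
#' EDSS change added to the baseline. Records with missing severity, baseline
#' or interval are skipped with the reason recorded in attribute
#' \code{"skipped"}. Predicted follow-up EDSS is continuous (not snapped to
#' the half-point grid) and clamped to [0, 10].
#'
#' @param msdss_pred CSF-predicted severity scores.
#' @param baseline_edss baseline EDSS (clinician- or MRI-derived).
#' @param interval_years follow-up interval in years (>= 0).
#' @param models a [conversion_models()] object.
#' @param participant_id optional ids (default sequence).
#' @param baseline_source \code{"clinician"} or \code{"mri"} (annotation
#'   only).
#' @return data.frame of class \code{prognostic_prediction} with all
#'   intermediates: \code{slope_cw}, \code{cw_base}, \code{delta_cw},
#'   \code{delta_edss}, \code{predicted_followup_edss}.
#' @export
predict_followup_edss <- function(msdss_pred, baseline_edss, interval_years,
                                  models, participant_id = NULL,
                                  baseline_source = "clinician") {
  stopifnot(inherits(models, "conversion_models"))
  n <- length(msdss_pred)
  if (length(baseline_edss) != n || length(interval_years) != n)
    stop_csf("inputs must be aligned vectors")
  if (any(interval_years < 0, na.rm = TRUE))
    stop_csf("interval_years must be >= 0")
  ids <- participant_id %||% as.character(seq_len(n))
  miss <- is.na(msdss_pred) | is.na(baseline_edss) | is.na(interval_years)
  reason <- character(n)
  reason[is.na(interval_years)] <- "missing interval"
  reason[is.na(baseline_edss)] <- "missing baseline EDSS"
  reason[is.na(msdss_pred)] <- "missing severity prediction"
  skipped <- data.frame(participant_id = ids[miss], reason = reason[miss],
                        stringsAsFactors = FALSE)

  sm <- models$slope; em <- models$edss
  slope_cw <- sm$a + sm$b * msdss_pred
  delta_cw <- slope_cw * interval_years
  cw_base <- suppressWarnings(edss_to_combiwise(baseline_edss, models))
  if (models$mode == "quadratic") {
    cw_target <- clamp(cw_base + delta_cw, em$domain[1], em$domain[2])
    clamped <- !miss & abs(cw_target - (cw_base + delta_cw)) > 1e-9
    if (any(clamped, na.rm = TRUE))
      warn_csf("%d record(s) hit the monotone-domain boundary; clamped",
               sum(clamped, na.rm = TRUE))
    delta_edss <- ifelse(delta_cw == 0, 0,
                         cw_to_edss_fitted(cw_target, em, warn = FALSE) -
                           cw_to_edss_fitted(cw_base, em, warn = FALSE))
  } else {
    delta_edss <- em$lin1 * delta_cw
  }
  predicted <- clamp(baseline_edss + delta_edss, 0, 10)
  out <- data.frame(
    participant_id = ids, baseline_source = baseline_source,
    baseline_edss = baseline_edss, msdss_pred = msdss_pred,
    interval_years = interval_years, slope_cw = slope_cw,
    cw_base = cw_base, delta_cw = delta_cw, delta_edss = delta_edss,
    predicted_followup_edss = predicted,
    stringsAsFactors = FALSE
  )[!miss, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("prognostic_prediction", "data.frame")
  out
}

#' Evaluate prognostic added value over baseline disability
#'
#' Spearman correlation between predicted and measured follow-up EDSS, and
#' the explained-variance gain of adding the CSF-predicted disability change
#' to a baseline-only linear model on identical cases. The gain p-value is
#' the two-sided t-test on the added term (equivalently the 1-df nested
#' F-test).
#'
#' @param predictions a [predict_followup_edss()] data.frame.
#' @param measured_followup measured follow-up EDSS aligned with
#'   \code{predictions} rows.
#' @return object of class \code{regression_report} with \code{spearman_rho},
#'   \code{spearman_p}, \code{r2_base}, \code{r2_augmented}, \code{p_gain},
#'   \code{coefficients}, \code{n}.
#' @export
evaluate_prognosis <- function(predictions, measured_followup) {
  stopifnot(inherits(predictions, "data.frame"))
  if (nrow(predictions) != length(measured_followup))
    stop_csf("predictions and measured follow-up must be aligned")
  keep <- stats::complete.cases(predictions$baseline_edss,
                                predictions$delta_edss,
                                predictions$predicted_followup_edss,
                                measured_followup)
  d <- predictions[keep, , drop = FALSE]
  y <- measured_followup[keep]
  if (nrow(d) < 10)
    stop_csf("prognostic evaluation needs >= 10 complete cases (got %d)", nrow(d))
  ct <- suppressWarnings(
    stats::cor.test(d$predicted_followup_edss, y, method = "spearman",
                    exact = FALSE))
  base_fit <- stats::lm(y ~ d$baseline_edss)
  r2_base <- summary(base_fit)$r.squared
  if (stats::sd(d$delta_edss) == 0) {
    r2_aug <- r2_base
    p_gain <- NA_real_
    coefs <- summary(base_fit)$coefficients
  } else {
    aug_fit <- stats::lm(y ~ d$baseline_edss + d$delta_edss)
    sa <- summary(aug_fit)
    r2_aug <- sa$r.squared
    p_gain <- sa$coefficients["d$delta_edss", "Pr(>|t|)"]
    coefs <- sa$coefficients
  }
  structure(
    list(spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
         r2_base = r2_base, r2_augmented = r2_aug, p_gain = p_gain,
         coefficients = coefs, n = nrow(d)),
    class = "regression_report"
  )
}

#' Multivariate model of follow-up disability
#'
#' OLS of measured follow-up EDSS on baseline EDSS, age and the CSF-predicted
#' progMS probability — the check that the staging classifier's probability
#' carries prognostic information beyond age and baseline disability.
#'
#' @param baseline_edss,age,progms_probability,measured_followup aligned
#'   numeric vectors; incomplete cases are dropped (>= 10 must remain).
#' @return a \code{regression_report} with per-term estimates, SEs and
#'   p-values, and the model R-squared.
#' @export
multivariate_followup_model <- function(baseline_edss, age, progms_probability,
                                        measured_followup) {
  d <- data.frame(followup = measured_followup, baseline = baseline_edss,
                  age = age, progms_prob = progms_probability)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    stop_csf("multivariate model needs >= 10 complete cases (got %d)", nrow(d))
  x <- cbind(1, d$baseline, d$age, d$progms_prob)
  if (kappa(x) > 1e8)
    warn_csf("near-collinear design (condition number %.2g)", kappa(x))
  fit <- stats::lm(followup ~ baseline + age + progms_prob, data = d)
  s <- summary(fit)
  structure(
    list(spearman_rho = NA_real_, spearman_p = NA_real_,
         r2_base = NA_real_, r2_augmented = s$r.squared, p_gain = NA_real_,
         r_squared = s$r.squared,
         coefficients = s$coefficients, n = nrow(d)),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Regression report (n = %d)\n", x$n))
  if (!is.na(x$spearman_rho))
    cat(sprintf("  Spearman rho %.2f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  if (!is.na(x$r2_base))
    cat(sprintf("  R2 %.0f%% (baseline) -> %.0f%% (+ predicted change), gain p = %.3g\n",
                100 * x$r2_base, 100 * x$r2_augmented, x$p_gain))
  if (!is.null(x$coefficients)) {
    cat("  coefficients:\n")
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

# Default semiquantitative-MRI-to-EDSS weights: a configurable linear
# stand-in for the published imaging model (whose coefficients are external
# to this package). Calibrated to the synthetic generator's MRI scores.
#' @rdname mri_baseline_edss
#' @export
default_mri_weights <- function() {
  v <- c(1.2, 0.8, 0.5)
  list(intercept = 0, coefficients = stats::setNames(v / sum(v^2),
                                                     paste0("mri_s", 1:3)))
}

#' MRI-derived baseline disability estimate
#'
#' Linear combination of semiquantitative MRI scores, clamped to the EDSS
#' range — a configurable stand-in for an imaging-based disability model,
#' serving as the alternative baseline entering the prognostic chain.
#'
#' @param mri_scores matrix/data.frame of score components (columns named as
#'   in \code{weights$coefficients}).
#' @param weights list with \code{intercept} and named \code{coefficients}.
#' @return numeric EDSS estimates in [0, 10].
#' @export
mri_baseline_edss <- function(mri_scores, weights = default_mri_weights()) {
  m <- as.matrix(mri_scores)
  need <- names(weights$coefficients)
  if (!all(need %in% colnames(m)))
    stop_csf("missing MRI score component(s): %s",
             paste(setdiff(need, colnames(m)), collapse = ", "))
  if (anyNA(m[, need])) stop_csf("missing values in MRI score components")
  est <- weights$intercept + as.numeric(m[, need, drop = FALSE] %*%
                                          weights$coefficients)
  clamp(est, 0, 10)
}
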