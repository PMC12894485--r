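# Age/sex-adjusted log-ratio feature engineering.
#
# Raw aptamer abundances (RFU) are log-transformed, residualized against a
# healthy reference for age and sex, and turned into the log-ratio features
# the classifiers consume. Ratios make the features invariant to any
# per-sample multiplicative rescaling of the assay, and the adjustment removes
# the demographic component of between-cohort differences.

#' Fit a healthy reference model for age/sex adjustment
#'
#' For every protein in the reference cohort, fits ordinary least squares of
#' \code{log(RFU)} on age and a male-sex indicator, storing the intercept,
#' age slope (log-RFU/year), sex offset (log-RFU, M vs F) and residual SD.
#'
#' @param reference a \code{csf_cohort} of healthy donors (>= 20 profiles,
#'   both sexes, non-degenerate ages).
#' @return object of class \code{healthy_reference}: list with
#'   \code{coefficients} (data.frame protein/intercept/age_slope/sex_offset/
#'   residual_sd) and \code{n_reference}.
#' @export
fit_healthy_reference <- function(reference) {
  stopifnot(inherits(reference, "csf_cohort"))
  pt <- reference$participants
  if (nrow(pt) < 20)
    stop_csf("healthy reference needs >= 20 profiles (got %d)", nrow(pt))
  if (anyNA(pt$age_at_lp) || anyNA(pt$sex))
    stop_csf("healthy reference requires age and sex for every donor")
  if (length(unique(pt$sex)) < 2)
    stop_csf("degenerate design: reference cohort contains a single sex")
  if (stats::sd(pt$age_at_lp) == 0)
    stop_csf("degenerate design: reference cohort has a single age")
  rfu <- as.matrix(reference$profiles[, -1, drop = FALSE])
  if (any(rfu <= 0)) stop_csf("non-positive RFU in reference profiles")
  y <- log(rfu)
  x <- cbind(1, pt$age_at_lp, as.numeric(pt$sex == "M"))
  fit <- stats::lm.fit(x, y)
  cf <- t(fit$coefficients)
  res <- as.matrix(fit$residuals)
  dfree <- nrow(x) - 3L
  rsd <- sqrt(colSums(res^2) / dfree)
  structure(
    list(coefficients = data.frame(
           protein = colnames(rfu),
           intercept = cf[, 1], age_slope = cf[, 2], sex_offset = cf[, 3],
           residual_sd = rsd, row.names = NULL, stringsAsFactors = FALSE),
         n_reference = nrow(pt)),
    class = "healthy_reference"
  )
}

#' @export
print.healthy_reference <- function(x, ...) {
  cat(sprintf("Healthy reference: %d proteins fitted on %d donors\n",
              nrow(x$coefficients), x$n_reference))
  cat(sprintf("  median |age slope| %.4f log-RFU/yr, median |sex offset| %.4f log-RFU\n",
              stats::median(abs(x$coefficients$age_slope)),
              stats::median(abs(x$coefficients$sex_offset))))
  invisible(x)
}

#' @export
coef.healthy_reference <- function(object, ...) {
  m <- as.matrix(object$coefficients[, c("intercept", "age_slope", "sex_offset")])
  rownames(m) <- object$coefficients$protein
  m
}

#' Age/sex-adjust a single proteomic profile
#'
#' The adjusted value is \code{log(RFU) - age_slope * age - sex_offset *
#' 1[sex == "M"]}; the reference intercept is retained (it cancels in
#' ratios).
#'
#' @param profile named numeric vector of positive RFU values.
#' @param age age in years.
#' @param sex \code{"F"} or \code{"M"}.
#' @param ref a [fit_healthy_reference()] object.
#' @return named numeric vector of adjusted log-abundances.
#' @export
adjust_profile <- function(profile, age, sex, ref) {
  stopifnot(inherits(ref, "healthy_reference"))
  if (is.null(names(profile)) || !is.numeric(profile))
    stop_csf("profile must be a named numeric vector of RFU values")
  if (any(!is.finite(profile)) || any(profile <= 0)) {
    bad <- names(profile)[!is.finite(profile) | profile <= 0]
    stop_csf("non-positive RFU for protein(s): %s", paste(bad, collapse = ", "))
  }
  if (!sex %in% c("F", "M")) stop_csf("sex must be 'F' or 'M'")
  idx <- match(names(profile), ref$coefficients$protein)
  if (anyNA(idx)) {
    stop_csf("protein(s) missing from healthy reference: %s",
             paste(names(profile)[is.na(idx)], collapse = ", "))
  }
  log(profile) - ref$coefficients$age_slope[idx] * age -
    ref$coefficients$sex_offset[idx] * as.numeric(sex == "M")
}

#' Age/sex-adjust every profile of a cohort
#'
#' @param cohort a \code{csf_cohort}.
#' @param ref a [fit_healthy_reference()] object covering the cohort's
#'   proteins.
#' @return numeric matrix (participants x proteins) of adjusted
#'   log-abundances, rownames = participant ids; carries the cohort's
#'   provenance tag as attribute \code{"cohort_tag"}.
#' @export
adjust_cohort <- function(cohort, ref) {
  stopifnot(inherits(cohort, "csf_cohort"), inherits(ref, "healthy_reference"))
  rfu <- as.matrix(cohort$profiles[, -1, drop = FALSE])
  if (any(rfu <= 0)) stop_csf("non-positive RFU in cohort profiles")
  idx <- match(colnames(rfu), ref$coefficients$protein)
  if (anyNA(idx)) {
    stop_csf("protein(s) missing from healthy reference: %s",
             paste(utils::head(colnames(rfu)[is.na(idx)], 10), collapse = ", "))
  }
  pt <- cohort$participants
  adj <- log(rfu) -
    outer(pt$age_at_lp, ref$coefficients$age_slope[idx]) -
    outer(as.numeric(pt$sex == "M"), ref$coefficients$sex_offset[idx])
  rownames(adj) <- pt$participant_id
  colnames(adj) <- colnames(rfu)
  attr(adj, "cohort_tag") <- cohort$provenance$tag
  adj
}

#' Compute log-ratio features for a panel
#'
#' The feature for ratio (A, B) is \code{adjusted(A) - adjusted(B)}; columns
#' are labelled \code{"A/B"} and ordered exactly as in the panel.
#'
#' @param adjusted matrix of adjusted log-abundances (participants x
#'   proteins) as returned by [adjust_cohort()], or a single named vector.
#' @param panel a \code{protein_panel}.
#' @return numeric matrix (participants x ratios) with attributes
#'   \code{"panel_name"} and (if present on the input) \code{"cohort_tag"}.
#' @export
compute_ratio_features <- function(adjusted, panel) {
  stopifnot(inherits(panel, "protein_panel"))
  if (is.null(dim(adjusted))) adjusted <- t(as.matrix(adjusted))
  missing <- setdiff(panel$proteins, colnames(adjusted))
  if (length(missing)) {
    stop_csf("panel '%s' protein(s) missing from adjusted data: %s",
             panel$name, paste(missing, collapse = ", "))
  }
  feats <- adjusted[, panel$ratios$numerator, drop = FALSE] -
    adjusted[, panel$ratios$denominator, drop = FALSE]
  colnames(feats) <- ratio_labels(panel)
  if (anyNA(feats)) stop_csf("missing values in feature matrix")
  attr(feats, "panel_name") <- panel$name
  attr(feats, "cohort_tag") <- attr(adjusted, "cohort_tag")
  feats
}

#' One-call feature construction for a cohort
#'
#' Convenience wrapper: [adjust_cohort()] followed by
#' [compute_ratio_features()].
#'
#' @inheritParams adjust_cohort
#' @inheritParams compute_ratio_features
#' @return feature matrix as from [compute_ratio_features()].
#' @export
cohort_features <- function(cohort, ref, panel) {
  compute_ratio_features(adjust_cohort(cohort, ref), panel)
}
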