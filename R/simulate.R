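# Synthetic multicenter cohort generator.
#
# The generator emulates the statistical structure the downstream validation
# assumes: class-dependent shifts in panel proteins, age/sex effects on
# log-abundance, a latent severity coupling severity-panel ratios to the rate
# of disability progression, EDSS measured on its clinical half-point grid,
# and per-center heterogeneity in class composition. Abundances are Gaussian
# on the natural-log scale and exponentiated to relative fluorescence units
# (RFU), so disease effects are additive on log scale and ratio features are
# Gaussian.

CSF_CLASSES <- c("RRMS", "ProgMS", "OIND", "NIND")

#' Simulation configuration for synthetic CSF cohorts
#'
#' Returns a validated configuration object holding every generative knob.
#' Defaults reproduce the conditions of a multicenter MS validation cohort:
#' 65 RRMS, 31 progressive MS, 30 inflammatory and 34 non-inflammatory
#' controls over 3 centers, with diagnostic and staging effect sizes
#' calibrated through [analytic_auc()] so that an efficient classifier attains
#' AUROC 0.94 (MS vs non-MS) and 0.76 (RRMS vs progMS), a ~10-year follow-up
#' interval, and disability progression of roughly one EDSS point per decade.
#'
#' Class signal is carried by unit-variance latent factors (one diagnostic,
#' one staging) whose means shift by \code{diag_effect}/\code{prog_effect} in
#' the affected classes. Panel proteins load on the factors with alternating
#' +1/2 and -1/2 coefficients along the panel's protein list, so a ratio of
#' two adjacent proteins carries the full factor with a unit coefficient and
#' the analytic AUROC ceiling of the cohort equals
#' \code{analytic_auc(effect)}. Latent severity is standard normal shifted by
#' +1 in progressive MS; the staging factor shares \code{sev_prog_cor} of its
#' variance with severity, so a higher predicted progMS probability also
#' anticipates faster progression.
#'
#' @param n_rrms,n_progms,n_oind,n_nind class counts (non-negative).
#' @param n_centers number of contributing centers.
#' @param center_props 4 x n_centers matrix of per-class center proportions
#'   (rows RRMS, ProgMS, OIND, NIND); defaults to the reference cohort's
#'   distribution for 3 centers, uniform otherwise.
#' @param diag_effect,prog_effect standardized log-abundance factor shifts for
#'   the diagnostic and staging panels.
#' @param severity_coupling slope linking latent severity to severity-panel
#'   ratios.
#' @param sev_prog_cor correlation between the staging factor and latent
#'   severity (within class).
#' @param age_slope_per_protein,sex_offset_per_protein log-RFU change per year
#'   of age and for male vs female sex, applied to every protein.
#' @param noise_sd residual log-abundance SD (measurement noise).
#' @param interval_mean_years,interval_sd_years,interval_min_years follow-up
#'   interval distribution (normal, truncated below at the minimum).
#' @param edss_noise_sd measurement noise SD on the EDSS scale.
#' @param n_noise_proteins number of exchangeable pure-noise proteins added to
#'   the proteome beyond the panel proteins.
#' @param missing_baseline_rate,missing_followup_rate,mri_rate per-MS-participant
#'   probabilities of a missing baseline EDSS, missing follow-up EDSS, and of
#'   having a baseline MRI.
#' @param slope_a,slope_b,slope_sd intercept, slope and residual SD of the
#'   true CombiWISE-slope model (CombiWISE units/year) in the severity score.
#' @param nonprogressor_floor_frac fraction of participants whose negative
#'   true slope is floored at 0, mimicking stable non-progressors.
#' @param cw_coef true quadratic coefficients (c0, c1, c2) of the
#'   CombiWISE-to-EDSS map used by the generator; monotone increasing on
#'   [0, 100] and mapping onto [0, 10] by default.
#' @param msdss_center,msdss_scale location and scale of the true severity
#'   score (monotone in latent severity).
#' @param baseline_intercept,baseline_sev_coef,baseline_age_coef,baseline_sd
#'   linear model of true baseline disability on latent severity and age.
#' @param age_mean,age_sd,age_range,sex_f_prop per-class demographics.
#' @param ocb_rate,igg_rate per-class positivity rates for oligoclonal bands
#'   and an elevated IgG index; \code{marker_obs_rate} gives the probability
#'   the markers were measured at all.
#' @param scd27_meanlog,scd27_load,scd27_sd,nfl_meanlog,nfl_load,nfl_sd
#'   lognormal models for the ancillary CSF markers (pg/mL); sCD27 loads on
#'   the diagnostic factor, NFL on latent severity.
#' @param panels named list of \code{protein_panel}s carrying signal
#'   (\code{diagnostic}, \code{progms}, \code{severity}).
#' @param seed default integer seed used when the generator functions are not
#'   given one explicitly.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_rrms = 65, n_progms = 31, n_oind = 30, n_nind = 34,
                       n_centers = 3, center_props = NULL,
                       diag_effect = sqrt(2) * stats::qnorm(0.94),
                       prog_effect = sqrt(2) * stats::qnorm(0.76),
                       severity_coupling = 1, sev_prog_cor = 0.5,
                       age_slope_per_protein = 0.005,
                       sex_offset_per_protein = 0.1,
                       noise_sd = 0.15,
                       interval_mean_years = 10.2, interval_sd_years = 4.5,
                       interval_min_years = 3,
                       edss_noise_sd = 1.7,
                       n_noise_proteins = 200,
                       missing_baseline_rate = 7 / 96,
                       missing_followup_rate = 5 / 96,
                       mri_rate = 54 / 96,
                       slope_a = 0.7, slope_b = 0.06, slope_sd = 1.2,
                       nonprogressor_floor_frac = 0.5,
                       cw_coef = c(0, 0.055, 0.00045),
                       msdss_center = 4, msdss_scale = 1.2,
                       baseline_intercept = 2.2, baseline_sev_coef = 0.9,
                       baseline_age_coef = 0.02, baseline_sd = 1.2,
                       age_mean = c(38.1, 51.0, 41.3, 39.7),
                       age_sd = c(10.7, 10.5, 13.2, 12.5),
                       age_range = c(18, 81),
                       sex_f_prop = c(44 / 65, 17 / 31, 20 / 30, 28 / 34),
                       ocb_rate = c(49 / 61, 23 / 29, 5 / 20, 0),
                       igg_rate = c(36 / 61, 14 / 28, 5 / 21, 0),
                       marker_obs_rate = c(0.94, 0.94, 0.68, 0.35),
                       scd27_meanlog = log(1000), scd27_load = 0.7,
                       scd27_sd = 0.3,
                       nfl_meanlog = log(800), nfl_load = 0.25, nfl_sd = 0.5,
                       panels = NULL, seed = 1L) {
  counts <- c(n_rrms, n_progms, n_oind, n_nind)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_csf("class counts must be non-negative integers")
  if (noise_sd <= 0) stop_csf("noise_sd must be > 0")
  if (edss_noise_sd < 0) stop_csf("edss_noise_sd must be >= 0")
  if (interval_mean_years <= 0) stop_csf("interval_mean_years must be > 0")
  if (n_centers < 1) stop_csf("n_centers must be >= 1")
  if (is.null(center_props)) {
    center_props <- if (n_centers == 3) {
      rbind(c(12, 6, 47) / 65, c(7, 18, 6) / 31,
            c(6, 5, 19) / 30, c(11, 4, 19) / 34)
    } else {
      matrix(1 / n_centers, 4, n_centers)
    }
  }
  center_props <- as.matrix(center_props)
  if (!all(dim(center_props) == c(4, n_centers)))
    stop_csf("center_props must be a 4 x n_centers matrix")
  if (is.null(panels)) {
    panels <- list(diagnostic = csf_panel("diagnostic"),
                   progms = csf_panel("progms"),
                   severity = csf_panel("severity"))
  }
  cfg <- list(
    n_rrms = n_rrms, n_progms = n_progms, n_oind = n_oind, n_nind = n_nind,
    n_centers = n_centers, center_props = center_props,
    diag_effect = diag_effect, prog_effect = prog_effect,
    severity_coupling = severity_coupling, sev_prog_cor = sev_prog_cor,
    age_slope_per_protein = age_slope_per_protein,
    sex_offset_per_protein = sex_offset_per_protein,
    noise_sd = noise_sd,
    interval_mean_years = interval_mean_years,
    interval_sd_years = interval_sd_years,
    interval_min_years = interval_min_years,
    edss_noise_sd = edss_noise_sd,
    n_noise_proteins = n_noise_proteins,
    missing_baseline_rate = missing_baseline_rate,
    missing_followup_rate = missing_followup_rate,
    mri_rate = mri_rate,
    slope_a = slope_a, slope_b = slope_b, slope_sd = slope_sd,
    nonprogressor_floor_frac = nonprogressor_floor_frac,
    cw_coef = cw_coef,
    msdss_center = msdss_center, msdss_scale = msdss_scale,
    baseline_intercept = baseline_intercept,
    baseline_sev_coef = baseline_sev_coef,
    baseline_age_coef = baseline_age_coef, baseline_sd = baseline_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    sex_f_prop = sex_f_prop,
    ocb_rate = ocb_rate, igg_rate = igg_rate,
    marker_obs_rate = marker_obs_rate,
    scd27_meanlog = scd27_meanlog, scd27_load = scd27_load,
    scd27_sd = scd27_sd,
    nfl_meanlog = nfl_meanlog, nfl_load = nfl_load, nfl_sd = nfl_sd,
    panels = panels, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Cheap deterministic tag of a configuration + seed, used for the
# external-validation provenance discipline (train and test cohorts must not
# share a tag).
config_hash <- function(config, seed, kind = "cohort") {
  cfg <- unclass(config)
  cfg$panels <- lapply(cfg$panels, function(p) p$ratios)
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10)
  h <- sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
  sprintf("%s-%d-%.0f", kind, as.integer(seed), h)
}

# Expected AUROC of the true quadratic map etc. -- the generator's disability
# forward model, shared by the longitudinal and cross-sectional simulators.
cw_forward <- function(cw, coef) coef[1] + coef[2] * cw + coef[3] * cw^2
cw_inverse_true <- function(edss, coef) {
  vapply(edss, function(e) {
    r <- quad_roots(coef[3], coef[2], coef[1] - e)
    r <- r[r >= -1e-9 & r <= 100 + 1e-9]
    if (!length(r)) NA_real_ else clamp(r[1], 0, 100)
  }, numeric(1))
}

#' Expected AUROC of a standardized class separation
#'
#' For two unit-variance normal score distributions whose means differ by
#' \code{effect}, the probability that a random positive outscores a random
#' negative is \eqn{\Phi(effect/\sqrt{2})}. Used to choose
#' \code{diag_effect}/\code{prog_effect} so simulated AUROCs land near a
#' target; [effect_for_auc()] is the inverse.
#'
#' @param effect standardized mean shift (finite, vectorized).
#' @return expected AUROC in [0, 1].
#' @export
#' @examples
#' analytic_auc(0)                      # 0.5
#' analytic_auc(effect_for_auc(0.94))   # 0.94
analytic_auc <- function(effect) {
  if (any(!is.finite(effect))) stop_csf("effect must be finite")
  stats::pnorm(effect / sqrt(2))
}

#' @rdname analytic_auc
#' @param target_auc AUROC in (0, 1) to calibrate an effect size for.
#' @export
effect_for_auc <- function(target_auc) {
  if (any(target_auc <= 0 | target_auc >= 1)) stop_csf("target_auc must be in (0,1)")
  sqrt(2) * stats::qnorm(target_auc)
}

# Draw per-participant demographics for a class vector.
draw_demographics <- function(class, config) {
  n <- length(class)
  ci <- match(class, CSF_CLASSES)
  age <- clamp(stats::rnorm(n, config$age_mean[ci], config$age_sd[ci]),
               config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_f_prop[ci], "F", "M")
  center <- integer(n)
  for (k in unique(ci)) {
    idx <- which(ci == k)
    center[idx] <- sample.int(config$n_centers, length(idx), replace = TRUE,
                              prob = config$center_props[k, ])
  }
  data.frame(age_at_lp = age, sex = sex, center = center,
             stringsAsFactors = FALSE)
}

# Alternating +1/2, -1/2 loadings over a panel's protein list, returned for
# the full protein universe (0 elsewhere). Proteins shared between panels
# accumulate loadings from each panel.
panel_loadings <- function(universe, panel) {
  l <- stats::setNames(numeric(length(universe)), universe)
  s <- rep(c(0.5, -0.5), length.out = length(panel$proteins))
  l[panel$proteins] <- l[panel$proteins] + s
  l
}

# Simulate the wide RFU table for given participants and latent factors.
simulate_profiles <- function(ids, age, sex, d, g, sev, config) {
  universe <- unique(c(unlist(lapply(config$panels, `[[`, "proteins")),
                       if (config$n_noise_proteins > 0)
                         sprintf("NP%03d", seq_len(config$n_noise_proteins))))
  n <- length(ids); p <- length(universe)
  mu <- protein_baseline_log(universe)
  l_diag <- panel_loadings(universe, config$panels$diagnostic)
  l_prog <- panel_loadings(universe, config$panels$progms)
  l_sev  <- panel_loadings(universe, config$panels$severity)
  m <- matrix(mu, n, p, byrow = TRUE)
  m <- m + config$age_slope_per_protein * (age - 45) +
    config$sex_offset_per_protein * (sex == "M")
  m <- m + d %o% l_diag + g %o% l_prog +
    (config$severity_coupling * sev) %o% l_sev
  m <- m + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  rfu <- exp(m)
  colnames(rfu) <- universe
  profiles <- data.frame(participant_id = ids, rfu, check.names = FALSE,
                         stringsAsFactors = FALSE)
  profiles
}

#' Generate a synthetic multicenter validation cohort
#'
#' Draws participants of the four diagnostic classes with demographics,
#' per-center assignment, ancillary CSF markers (OCB, IgG index, sCD27, NFL),
#' an EDSS timeline for the MS classes (controls are not followed, so their
#' EDSS fields are missing), an optional MRI-derived baseline disability
#' estimate, and a wide protein-abundance table carrying the configured class
#' signal. Output is byte-identical for identical \code{(config, seed)}.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to \code{config$seed}. Sub-streams for
#'   demographics, latent factors, markers, the EDSS timeline and the proteome
#'   are derived deterministically from it.
#' @param id_prefix prefix for participant identifiers.
#' @return an object of class \code{csf_cohort}: list with
#'   \code{participants} (one row per participant), \code{profiles} (wide RFU
#'   table), \code{mri_scores} (semiquantitative MRI scores for the subset
#'   with imaging) and \code{provenance} (config, seed, tag and the true
#'   generative parameters).
#' @export
generate_cohort <- function(config, seed = config$seed, id_prefix = "P") {
  stopifnot(inherits(config, "sim_config"))
  counts <- c(config$n_rrms, config$n_progms, config$n_oind, config$n_nind)
  n <- sum(counts)
  if (n == 0) stop_csf("empty cohort: all class counts are zero")
  class <- rep(CSF_CLASSES, counts)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  is_ms <- class %in% c("RRMS", "ProgMS")
  is_prog <- class == "ProgMS"

  demo <- with_seed(sub_seed(seed, 1), draw_demographics(class, config))

  lat <- with_seed(sub_seed(seed, 2), {
    sev_resid <- stats::rnorm(n)
    list(
      sev_resid = sev_resid,
      severity = sev_resid + as.numeric(is_prog),
      d = config$diag_effect * as.numeric(is_ms) + stats::rnorm(n),
      g = config$prog_effect * as.numeric(is_prog) +
        config$sev_prog_cor * sev_resid +
        sqrt(max(0, 1 - config$sev_prog_cor^2)) * stats::rnorm(n)
    )
  })

  mk <- with_seed(sub_seed(seed, 3), {
    ci <- match(class, CSF_CLASSES)
    ocb <- stats::runif(n) < config$ocb_rate[ci]
    igg <- stats::runif(n) < config$igg_rate[ci]
    obs <- stats::runif(n) < config$marker_obs_rate[ci]
    ocb[!obs] <- NA; igg[!obs] <- NA
    scd27 <- exp(config$scd27_meanlog + config$scd27_load * lat$d +
                   stats::rnorm(n, 0, config$scd27_sd))
    nfl <- exp(config$nfl_meanlog + config$nfl_load * lat$severity +
                 stats::rnorm(n, 0, config$nfl_sd))
    list(ocb = ocb, igg = igg, scd27 = scd27, nfl = nfl)
  })

  tl <- with_seed(sub_seed(seed, 4), {
    msdss_true <- config$msdss_center + config$msdss_scale * lat$severity
    slope <- config$slope_a + config$slope_b * msdss_true +
      stats::rnorm(n, 0, config$slope_sd)
    floored <- stats::runif(n) < config$nonprogressor_floor_frac
    slope[floored] <- pmax(slope[floored], 0)
    interval <- pmax(stats::rnorm(n, config$interval_mean_years,
                                  config$interval_sd_years),
                     config$interval_min_years)
    base_true <- clamp(config$baseline_intercept +
                         config$baseline_sev_coef * lat$severity +
                         config$baseline_age_coef * (demo$age_at_lp - 40) +
                         stats::rnorm(n, 0, config$baseline_sd), 0, 10)
    qc <- config$cw_coef
    rng <- cw_forward(c(0, 100), qc)
    cw_base <- cw_inverse_true(clamp(base_true, rng[1], rng[2]), qc)
    cw_fu <- clamp(cw_base + slope * interval, 0, 100)
    fu_true <- cw_forward(cw_fu, qc)
    base_meas <- edss_grid_round(base_true + stats::rnorm(n, 0, config$edss_noise_sd))
    fu_meas <- edss_grid_round(fu_true + stats::rnorm(n, 0, config$edss_noise_sd))
    has_mri <- is_ms & stats::runif(n) < config$mri_rate
    v <- c(1.2, 0.8, 0.5)
    scores <- sapply(v, function(vk) vk * base_true + stats::rnorm(n, 0, 0.8))
    colnames(scores) <- paste0("mri_s", seq_along(v))
    mri_est <- mri_baseline_edss(scores, default_mri_weights())
    list(msdss_true = msdss_true, slope = slope, interval = interval,
         base_true = base_true, fu_true = fu_true,
         base_meas = base_meas, fu_meas = fu_meas,
         has_mri = has_mri, scores = scores, mri_est = mri_est)
  })

  miss <- with_seed(sub_seed(seed, 6), {
    list(base = stats::runif(n) < config$missing_baseline_rate,
         fu = stats::runif(n) < config$missing_followup_rate)
  })

  baseline_edss <- ifelse(is_ms & !miss$base, tl$base_meas, NA_real_)
  followup_edss <- ifelse(is_ms & !miss$fu, tl$fu_meas, NA_real_)
  interval_years <- ifelse(is_ms, tl$interval, NA_real_)
  mri_edss <- ifelse(tl$has_mri, tl$mri_est, NA_real_)

  participants <- data.frame(
    participant_id = ids,
    center = demo$center,
    diagnosis = factor(class, levels = CSF_CLASSES),
    age_at_lp = demo$age_at_lp,
    sex = demo$sex,
    baseline_edss = baseline_edss,
    followup_edss = followup_edss,
    interval_years = interval_years,
    ocb_positive = mk$ocb,
    igg_index_elevated = mk$igg,
    mri_edss_estimate = mri_edss,
    scd27 = mk$scd27,
    nfl = mk$nfl,
    latent_severity = lat$severity,
    stringsAsFactors = FALSE
  )

  profiles <- with_seed(
    sub_seed(seed, 5),
    simulate_profiles(ids, demo$age_at_lp, demo$sex,
                      lat$d, lat$g, lat$severity, config)
  )

  truth <- data.frame(
    participant_id = ids,
    msdss_true = tl$msdss_true,
    combiwise_slope_true = tl$slope,
    baseline_edss_true = tl$base_true,
    followup_edss_true = tl$fu_true,
    diag_factor = lat$d,
    prog_factor = lat$g,
    stringsAsFactors = FALSE
  )

  structure(
    list(participants = participants,
         profiles = profiles,
         mri_scores = data.frame(participant_id = ids, tl$scores,
                                 stringsAsFactors = FALSE)[tl$has_mri, ,
                                                           drop = FALSE],
         provenance = list(config = config, seed = as.integer(seed),
                           tag = config_hash(config, seed),
                           truth = truth,
                           truth_params = list(
                             slope_a = config$slope_a,
                             slope_b = config$slope_b,
                             cw_coef = config$cw_coef))),
    class = "csf_cohort"
  )
}

#' Generate a healthy reference cohort for age/sex adjustment
#'
#' Profiles carry only age and sex effects plus measurement noise; no disease
#' signal. The diagnosis field is set to \code{"Healthy"}, a category outside
#' the classifier classes. At least 20 participants are required so the
#' per-protein age/sex regressions are identifiable with some margin.
#'
#' @param n number of reference donors (>= 20).
#' @param age_range ages are drawn uniformly over this range.
#' @inheritParams generate_cohort
#' @return a \code{csf_cohort} with diagnosis \code{"Healthy"} for every row.
#' @export
generate_healthy_reference <- function(n, age_range = c(20, 60),
                                       config = sim_config(),
                                       seed = config$seed) {
  if (n < 20)
    stop_csf("healthy reference needs n >= 20 (got %d) to fit age/sex models", n)
  ids <- sprintf("H%04d", seq_len(n))
  demo <- with_seed(sub_seed(seed, 11), {
    data.frame(age_at_lp = stats::runif(n, age_range[1], age_range[2]),
               sex = ifelse(stats::runif(n) < 0.5, "F", "M"),
               center = 1L, stringsAsFactors = FALSE)
  })
  zero <- numeric(n)
  profiles <- with_seed(
    sub_seed(seed, 12),
    simulate_profiles(ids, demo$age_at_lp, demo$sex, zero, zero, zero, config)
  )
  participants <- data.frame(
    participant_id = ids, center = demo$center,
    diagnosis = factor(rep("Healthy", n)),
    age_at_lp = demo$age_at_lp, sex = demo$sex,
    baseline_edss = NA_real_, followup_edss = NA_real_,
    interval_years = NA_real_, ocb_positive = NA,
    igg_index_elevated = NA, mri_edss_estimate = NA_real_,
    scd27 = NA_real_, nfl = NA_real_, latent_severity = 0,
    stringsAsFactors = FALSE
  )
  structure(
    list(participants = participants, profiles = profiles,
         mri_scores = NULL,
         provenance = list(config = config, seed = as.integer(seed),
                           tag = config_hash(config, seed, "healthy"),
                           truth = NULL, truth_params = NULL)),
    class = "csf_cohort"
  )
}

#' Generate an MS-only training cohort with severity targets
#'
#' Emulates the single-center longitudinal cohort used to adapt the
#' classifiers: MS participants only (\code{n_rrms} + \code{n_progms} from the
#' config), with the true severity score \code{msdss_true} (monotone in latent
#' severity) and the observed progression slope \code{combiwise_slope_true}
#' (\code{slope_a + slope_b * msdss_true} plus noise) exposed as participant
#' columns for training the severity regressor and the slope conversion
#' model. The generating \code{(slope_a, slope_b)} are recorded in
#' \code{provenance$truth_params} for recovery tests.
#'
#' @inheritParams generate_cohort
#' @return a \code{csf_cohort}; participants carry \code{msdss_true} and
#'   \code{combiwise_slope_true}.
#' @export
generate_training_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$n_oind <- 0L
  cfg$n_nind <- 0L
  if (cfg$n_rrms + cfg$n_progms == 0)
    stop_csf("empty cohort: training cohort needs MS participants")
  cohort <- generate_cohort(cfg, seed = seed, id_prefix = "T")
  cohort$participants$msdss_true <- cohort$provenance$truth$msdss_true
  cohort$participants$combiwise_slope_true <-
    cohort$provenance$truth$combiwise_slope_true
  cohort$provenance$tag <- config_hash(cfg, seed, "training")
  cohort
}

#' Simulate a cross-sectional disability dataset (CombiWISE vs EDSS)
#'
#' Visit-level pairs of the continuous 0-100 disability scale and the EDSS it
#' maps to under the generator's true monotone quadratic, plus measurement
#' noise. Used to fit the CombiWISE-to-EDSS conversion of the prognostic
#' chain.
#'
#' @param n number of visits.
#' @inheritParams generate_cohort
#' @return data.frame with columns \code{combiwise}, \code{edss}.
#' @export
simulate_disability_crosssection <- function(n, config = sim_config(),
                                             seed = config$seed) {
  with_seed(sub_seed(seed, 21), {
    cw <- stats::runif(n, 0, 100)
    edss <- clamp(cw_forward(cw, config$cw_coef) +
                    stats::rnorm(n, 0, config$edss_noise_sd), 0, 10)
    data.frame(combiwise = cw, edss = edss)
  })
}

#' @export
print.csf_cohort <- function(x, ...) {
  tab <- table(x$participants$diagnosis)
  cat(sprintf("Synthetic CSF cohort: %d participants, %d proteins\n",
              nrow(x$participants), ncol(x$profiles) - 1L))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  cat("  provenance: ", x$provenance$tag, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk as plain-text tables
#'
#' Writes \code{participants.csv} (one row per participant, missing values as
#' empty cells), \code{proteomics.csv} (wide RFU table) and a
#' \code{cohort.json} sidecar recording the configuration, seed and true
#' generative parameters.
#'
#' @param cohort a \code{csf_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "csf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$profiles, file.path(dir, "proteomics.csv"),
                   row.names = FALSE, na = "")
  prov <- cohort$provenance
  side <- list(
    seed = prov$seed, tag = prov$tag,
    truth_params = prov$truth_params,
    config = {
      cfg <- prov$config
      cfg$panels <- lapply(cfg$panels, function(p) p$ratios)
      unclass(cfg)
    }
  )
  jsonlite::write_json(side, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#' @param dir directory holding \code{participants.csv} and
#'   \code{proteomics.csv}.
#' @return a \code{csf_cohort} with file-origin provenance.
#' @export
read_cohort <- function(dir) {
  pf <- file.path(dir, "participants.csv")
  qf <- file.path(dir, "proteomics.csv")
  if (!file.exists(pf) || !file.exists(qf))
    stop_csf("cohort directory %s must contain participants.csv and proteomics.csv", dir)
  participants <- utils::read.csv(pf, stringsAsFactors = FALSE, na.strings = "")
  participants$diagnosis <- factor(participants$diagnosis,
                                   levels = union(CSF_CLASSES,
                                                  unique(participants$diagnosis)))
  profiles <- utils::read.csv(qf, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(participants$participant_id))
    stop_csf("duplicate participant ids in %s", pf)
  structure(
    list(participants = participants, profiles = profiles, mri_scores = NULL,
         provenance = list(config = NULL, seed = NA_integer_,
                           tag = paste0("file-", normalizePath(dir)),
                           truth = NULL, truth_params = NULL)),
    class = "csf_cohort"
  )
}
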