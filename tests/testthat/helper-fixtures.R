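# Shared fixtures, built once per test run.

# Small, fast configuration used where the exact cohort scale does not matter.
small_config <- function(...) {
  sim_config(n_rrms = 30, n_progms = 15, n_oind = 12, n_nind = 15,
             n_noise_proteins = 20, ...)
}

# Build a csf_cohort by hand from a participants data.frame and an RFU matrix
# (rows = participants). Used for exactly-determined regression cases.
manual_cohort <- function(participants, rfu, tag = "manual") {
  structure(
    list(participants = participants,
         profiles = data.frame(participant_id = participants$participant_id,
                               rfu, check.names = FALSE,
                               stringsAsFactors = FALSE),
         mri_scores = NULL,
         provenance = list(config = NULL, seed = NA_integer_, tag = tag,
                           truth = NULL, truth_params = NULL)),
    class = "csf_cohort"
  )
}

manual_participants <- function(n, age, sex, diagnosis = "Healthy") {
  data.frame(
    participant_id = sprintf("M%03d", seq_len(n)),
    center = 1L, diagnosis = factor(rep_len(diagnosis, n)),
    age_at_lp = age, sex = sex,
    baseline_edss = NA_real_, followup_edss = NA_real_,
    interval_years = NA_real_, ocb_positive = NA, igg_index_elevated = NA,
    mri_edss_estimate = NA_real_, scd27 = NA_real_, nfl = NA_real_,
    latent_severity = 0, stringsAsFactors = FALSE
  )
}

# Brute-force AUROC oracle: explicit loop over all positive x negative pairs.
brute_force_auc <- function(scores, pos) {
  sp <- scores[pos]; sm <- scores[!pos]
  total <- 0
  for (x in sp) for (y in sm) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(sp) * length(sm))
}

# Exact Mann-Whitney enumeration oracle, written independently of the package
# implementation (iterates assignments via combn and recomputes rank sums).
enumeration_p_oracle <- function(scores, pos) {
  n <- length(scores); n1 <- sum(pos)
  r <- rank(scores)
  obs <- sum(r[pos])
  sets <- utils::combn(n, n1)
  hits <- 0
  for (j in seq_len(ncol(sets))) {
    if (sum(r[sets[, j]]) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(sets)
}

# A fitted conversion-model pair with known coefficients (no fitting noise),
# for chain arithmetic tests.
known_conversion <- function(a = 0.5, b = 0.1, c0 = 0, c1 = 0.055,
                             c2 = 0.00045, mode = "quadratic") {
  sm <- structure(list(a = a, b = b, se = c(0, 0), r_squared = 1, sigma = 0,
                       n = 99), class = "msdss_slope_model")
  em <- structure(list(c0 = c0, c1 = c1, c2 = c2,
                       domain = c(if (c2 > 0) max(0, -c1 / (2 * c2)) else 0,
                                  if (c2 < 0) min(100, -c1 / (2 * c2)) else 100),
                       lin0 = 0, lin1 = c1, r_squared = 1, sigma = 0, n = 99),
                  class = "combiwise_edss_model")
  conversion_models(sm, em, mode = mode)
}

# Write a synthetic supplementary-results-style CSV (per-participant model
# outputs) and return its path plus the table itself.
write_synthetic_supplementary <- function(path, n_rrms = 65, n_progms = 31,
                                          n_oind = 30, n_nind = 34,
                                          seed = 99, with_edss = TRUE) {
  set.seed(seed)
  dx <- rep(c("RRMS", "ProgMS", "OIND", "NIND"),
            c(n_rrms, n_progms, n_oind, n_nind))
  n <- length(dx)
  is_ms <- dx %in% c("RRMS", "ProgMS")
  ms_p <- round(plogis(stats::rnorm(n, ifelse(is_ms, 2.5, -1.5), 1.5)), 4)
  prog_p <- round(plogis(stats::rnorm(n, ifelse(dx == "ProgMS", 1, -0.8), 1.2)), 4)
  d <- data.frame(
    id = sprintf("S%03d", seq_len(n)), dx_label = dx,
    prob_ms = ms_p, prob_progms = ifelse(is_ms, prog_p, NA),
    msdss = round(ifelse(is_ms, stats::rnorm(n, 4, 1.2), NA), 3),
    center = sample(1:3, n, replace = TRUE),
    age = round(stats::runif(n, 18, 70), 1),
    ocb = ifelse(stats::runif(n) < 0.85,
                 ifelse(is_ms, stats::runif(n) < 0.8, stats::runif(n) < 0.15), NA),
    igg = ifelse(stats::runif(n) < 0.85,
                 ifelse(is_ms, stats::runif(n) < 0.6, stats::runif(n) < 0.15), NA),
    stringsAsFactors = FALSE
  )
  if (with_edss) {
    d$edss0 <- ifelse(is_ms, edss_grid_round(stats::runif(n, 0, 6)), NA)
    d$edss1 <- ifelse(is_ms, edss_grid_round(d$edss0 + stats::rnorm(n, 1, 1)), NA)
    d$years <- ifelse(is_ms, round(stats::runif(n, 3, 15), 1), NA)
  }
  utils::write.csv(d, path, row.names = FALSE, na = "")
  d
}

supplementary_column_map <- c(
  participant_id = "id", diagnosis = "dx_label", ms_probability = "prob_ms",
  progms_probability = "prob_progms", msdss_pred = "msdss", center = "center",
  age_at_lp = "age", ocb_positive = "ocb", igg_index_elevated = "igg",
  baseline_edss = "edss0", followup_edss = "edss1", interval_years = "years")
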