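# End-to-end validation pipeline: simulate-or-load, build features, train on
# the training cohorts, predict on the external validation cohort, run ROC
# inference, the prognostic chain and the misclassification audit, and
# assemble a reproducible report.

#' Pipeline configuration
#'
#' Exactly one mode is active. In \code{"simulate"} mode everything is
#' generated by the package's cohort simulator; \code{"supplementary"} mode
#' consumes a per-participant results table (precomputed model probabilities
#' and severity predictions); \code{"user_data"} mode reads a cohort written
#' with [write_cohort()] and scores it with synthetically trained models.
#'
#' @param mode one of \code{"simulate"}, \code{"supplementary"},
#'   \code{"user_data"}.
#' @param sim a [sim_config()] describing the validation cohort (and, scaled
#'   by \code{train_multiplier}, the classifier training cohort).
#' @param train_multiplier class counts of the training cohort are the
#'   validation counts times this factor.
#' @param n_severity_training MS participants in the severity training
#'   cohort.
#' @param n_reference healthy donors for the age/sex reference.
#' @param n_crosssection visits for the CombiWISE-to-EDSS conversion fit.
#' @param n_trees forest size for all models.
#' @param n_boot,level bootstrap replicates and confidence level for AUROC
#'   CIs.
#' @param seed master seed; all stage seeds are derived from it.
#' @param supplementary_path path to the results CSV (supplementary mode).
#' @param column_map column mapping for [read_supplementary_results()].
#' @param conversion optional prefitted [conversion_models()] (needed for the
#'   prognostic stage in supplementary mode).
#' @param cohort_dir cohort directory (user_data mode).
#' @param out_dir optional directory; when set, the report JSON and
#'   intermediate CSV tables are written there.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("simulate", "supplementary", "user_data"),
                            sim = sim_config(), train_multiplier = 3,
                            n_severity_training = 300, n_reference = 150,
                            n_crosssection = 3000, n_trees = 500,
                            n_boot = 2000, level = 0.95, seed = 1L,
                            supplementary_path = NULL, column_map = NULL,
                            conversion = NULL, cohort_dir = NULL,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "supplementary" && is.null(supplementary_path))
    stop_csf("supplementary mode needs supplementary_path")
  if (mode == "user_data" && is.null(cohort_dir))
    stop_csf("user_data mode needs cohort_dir")
  structure(list(mode = mode, sim = sim, train_multiplier = train_multiplier,
                 n_severity_training = n_severity_training,
                 n_reference = n_reference, n_crosssection = n_crosssection,
                 n_trees = n_trees, n_boot = n_boot, level = level,
                 seed = as.integer(seed),
                 supplementary_path = supplementary_path,
                 column_map = column_map, conversion = conversion,
                 cohort_dir = cohort_dir, out_dir = out_dir),
            class = "pipeline_config")
}

# Single formatting layer for reported p-values (scientific, 2 significant
# digits) so report diffs are stable.
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_, sprintf("%.1e", p))
}

#' Run the full validation
#'
#' Executes the stages in order with external-validation discipline (models
#' are never evaluated on the cohort they were trained on): reference fit,
#' feature construction, classifier/severity training, prediction on the
#' validation cohort, diagnostic and staging ROC inference, comparison with
#' conventional CSF markers, the staging multivariate model, the prognostic
#' chain under clinician- and MRI-derived baselines, and the
#' misclassification audit. Rerunning with the same configuration reproduces
#' every number.
#'
#' @param config a [pipeline_config()].
#' @return object of class \code{validation_report}.
#' @export
run_full_validation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  switch(config$mode,
    simulate = run_validation_simulate(config),
    supplementary = {
      sup <- read_supplementary_results(config$supplementary_path,
                                        config$column_map)
      assemble_report(sup, config, conv = config$conversion,
                      mode = "supplementary")
    },
    user_data = {
      cohort <- read_cohort(config$cohort_dir)
      fit <- train_validation_models(config)
      preds <- score_cohort(cohort, fit)
      assemble_report(preds, config, conv = fit$conversion, mode = "user_data")
    }
  )
}

# Train reference, classifiers, severity regressor and conversion models from
# synthetic training material.
train_validation_models <- function(config) {
  seed <- config$seed
  sim <- config$sim
  reference <- generate_healthy_reference(config$n_reference,
                                          config = sim,
                                          seed = sub_seed(seed, 101))
  ref <- fit_healthy_reference(reference)

  train_cfg <- sim
  for (f in c("n_rrms", "n_progms", "n_oind", "n_nind"))
    train_cfg[[f]] <- as.integer(round(sim[[f]] * config$train_multiplier))
  train_cohort <- generate_cohort(train_cfg, seed = sub_seed(seed, 102),
                                  id_prefix = "TR")

  sev_cfg <- sim
  sev_cfg$n_rrms <- as.integer(round(config$n_severity_training * 2 / 3))
  sev_cfg$n_progms <- config$n_severity_training - sev_cfg$n_rrms
  sev_cohort <- generate_training_cohort(sev_cfg, seed = sub_seed(seed, 103))

  tr_pt <- train_cohort$participants
  ms_labels <- factor(ifelse(tr_pt$diagnosis %in% c("RRMS", "ProgMS"),
                             "MS", "nonMS"), levels = c("nonMS", "MS"))
  diag_feats <- cohort_features(train_cohort, ref, sim$panels$diagnostic)
  ms_model <- train_classifier(diag_feats, ms_labels, positive = "MS",
                               model_kind = "ms_vs_nonms",
                               n_trees = config$n_trees,
                               seed = sub_seed(seed, 106))

  ms_rows <- tr_pt$diagnosis %in% c("RRMS", "ProgMS")
  prog_feats <- cohort_features(train_cohort, ref, sim$panels$progms)
  prog_model <- train_classifier(prog_feats[ms_rows, , drop = FALSE],
                                 droplevels(tr_pt$diagnosis[ms_rows]),
                                 positive = "ProgMS",
                                 model_kind = "rrms_vs_progms",
                                 n_trees = config$n_trees,
                                 seed = sub_seed(seed, 107))

  sev_feats <- cohort_features(sev_cohort, ref, sim$panels$severity)
  sev_model <- train_severity_regressor(sev_feats,
                                        sev_cohort$participants$msdss_true,
                                        n_trees = config$n_trees,
                                        seed = sub_seed(seed, 108))

  # conversion models: slope fit uses the severity forest's out-of-bag
  # severity predictions against the observed training slopes; the
  # CombiWISE<->EDSS quadratic comes from a cross-sectional dataset
  slope_model <- fit_msdss_slope_model(
    sev_model$oob_prediction, sev_cohort$participants$combiwise_slope_true)
  cross <- simulate_disability_crosssection(config$n_crosssection, sim,
                                            seed = sub_seed(seed, 105))
  edss_model <- fit_combiwise_edss_model(cross$combiwise, cross$edss)
  conv <- conversion_models(slope_model, edss_model)

  list(reference = ref, ms_model = ms_model, prog_model = prog_model,
       sev_model = sev_model, conversion = conv,
       tags = list(train = train_cohort$provenance$tag,
                   severity = sev_cohort$provenance$tag))
}

# Score an external cohort with the fitted models, returning the standardized
# per-participant table the report assembly consumes.
score_cohort <- function(cohort, fit) {
  pt <- cohort$participants
  if (identical(cohort$provenance$tag, fit$tags$train) ||
      identical(cohort$provenance$tag, fit$tags$severity))
    stop_csf("external-validation discipline violated: evaluation cohort %s was used for training",
             cohort$provenance$tag)
  ref <- fit$reference
  sim_panels <- list(
    diagnostic = fit$ms_model, progms = fit$prog_model, severity = fit$sev_model)
  adj <- adjust_cohort(cohort, ref)
  ms_prob <- predict_probabilities(
    fit$ms_model,
    compute_ratio_features(adj, panel_from_model(fit$ms_model)))$probability
  prog_prob <- predict_probabilities(
    fit$prog_model,
    compute_ratio_features(adj, panel_from_model(fit$prog_model)))$probability
  msdss <- predict_probabilities(
    fit$sev_model,
    compute_ratio_features(adj, panel_from_model(fit$sev_model)))$prediction
  data.frame(
    participant_id = pt$participant_id,
    diagnosis = as.character(pt$diagnosis),
    center = pt$center,
    age_at_lp = pt$age_at_lp,
    sex = pt$sex,
    baseline_edss = pt$baseline_edss,
    followup_edss = pt$followup_edss,
    interval_years = pt$interval_years,
    mri_edss_estimate = pt$mri_edss_estimate,
    ocb_positive = pt$ocb_positive,
    igg_index_elevated = pt$igg_index_elevated,
    scd27 = pt$scd27, nfl = pt$nfl,
    ms_probability = ms_prob, progms_probability = prog_prob,
    msdss_pred = msdss,
    stringsAsFactors = FALSE
  )
}

# Reconstruct the ratio panel a model was trained on from its feature names.
panel_from_model <- function(model) {
  parts <- strsplit(model$feature_names, "/", fixed = TRUE)
  structure(
    list(name = model$panel_name %||% "model",
         ratios = data.frame(numerator = vapply(parts, `[`, "", 1),
                             denominator = vapply(parts, `[`, "", 2),
                             stringsAsFactors = FALSE),
         proteins = unique(unlist(parts))),
    class = "protein_panel"
  )
}

run_validation_simulate <- function(config) {
  fit <- train_validation_models(config)
  val_cohort <- generate_cohort(config$sim, seed = sub_seed(config$seed, 104),
                                id_prefix = "V")
  preds <- score_cohort(val_cohort, fit)
  rep <- assemble_report(preds, config, conv = fit$conversion,
                         mode = "simulate")
  rep$meta$tags <- c(fit$tags, validation = val_cohort$provenance$tag)
  rep$meta$models <- list(
    ms_oob_auroc = fit$ms_model$oob_auroc,
    progms_oob_auroc = fit$prog_model$oob_auroc,
    conversion = coef(fit$conversion))
  if (!is.null(config$out_dir)) write_report(rep, preds, config$out_dir)
  rep
}

# All reported numbers for a standardized per-participant table.
assemble_report <- function(d, config, conv = NULL, mode = "simulate") {
  seed <- config$seed
  is_ms <- d$diagnosis %in% c("RRMS", "ProgMS")
  log <- list(n_total = nrow(d), n_ms = sum(is_ms), n_nonms = sum(!is_ms))

  diag_roc <- bootstrap_auc_ci(d$ms_probability, is_ms,
                               n_boot = config$n_boot, level = config$level,
                               seed = sub_seed(seed, 109))
  diag_roc$p_value <- mason_graham_p(d$ms_probability, is_ms)
  per_center <- if (!all(is.na(d$center))) {
    auroc_by_group(d$ms_probability, is_ms, d$center)$by_group
  }
  diagnostic <- list(
    roc = diag_roc, per_center = per_center,
    confusion = confusion_at_cutoff(d$ms_probability, is_ms, cutoff = 0.5),
    median_prob_ms = stats::median(d$ms_probability[is_ms]),
    median_prob_nonms = stats::median(d$ms_probability[!is_ms]))

  staging <- NULL
  if (!all(is.na(d$progms_probability)) && sum(is_ms) >= 4) {
    dm <- d[is_ms, , drop = FALSE]
    st_roc <- bootstrap_auc_ci(dm$progms_probability, dm$diagnosis == "ProgMS",
                               n_boot = config$n_boot, level = config$level,
                               seed = sub_seed(seed, 110))
    st_roc$p_value <- mason_graham_p(dm$progms_probability,
                                     dm$diagnosis == "ProgMS")
    multi <- tryCatch(
      multivariate_followup_model(dm$baseline_edss, dm$age_at_lp,
                                  dm$progms_probability, dm$followup_edss),
      error = function(e) NULL)
    staging <- list(
      roc = st_roc,
      median_prob_progms = stats::median(dm$progms_probability[dm$diagnosis == "ProgMS"]),
      median_prob_rrms = stats::median(dm$progms_probability[dm$diagnosis == "RRMS"]),
      multivariate = multi)
  }

  markers <- tryCatch(
    compare_with_conventional_markers(d$ms_probability, is_ms,
                                      d$ocb_positive, d$igg_index_elevated),
    error = function(e) NULL)

  prognostic <- list(available = FALSE)
  if (!is.null(conv) && !all(is.na(d$msdss_pred)) &&
      !all(is.na(d$followup_edss))) {
    dm <- d[is_ms, , drop = FALSE]
    evaluate_source <- function(baseline, source) {
      pr <- suppressWarnings(
        predict_followup_edss(dm$msdss_pred, baseline, dm$interval_years,
                              conv, participant_id = dm$participant_id,
                              baseline_source = source))
      measured <- dm$followup_edss[match(pr$participant_id, dm$participant_id)]
      list(predictions = pr,
           report = tryCatch(evaluate_prognosis(pr, measured),
                             error = function(e) NULL))
    }
    clin <- evaluate_source(dm$baseline_edss, "clinician")
    mri <- if (!all(is.na(dm$mri_edss_estimate)))
      evaluate_source(dm$mri_edss_estimate, "mri")
    prognostic <- list(available = !is.null(clin$report),
                       clinician = clin$report,
                       mri = if (!is.null(mri)) mri$report,
                       predictions = rbind(clin$predictions,
                                           if (!is.null(mri)) mri$predictions))
  }

  audit <- misclassification_audit(d, cutoff = 0.5)

  structure(
    list(diagnostic = diagnostic, staging = staging, markers = markers,
         prognostic = prognostic, misclassified = audit, log = log,
         meta = list(mode = mode, seed = seed,
                     config_hash = config_hash(config$sim, seed, "pipeline"))),
    class = "validation_report"
  )
}

#' Compare the molecular classifier with conventional CSF markers
#'
#' Restricted to participants with both oligoclonal-band and IgG-index
#' results, computes AUROCs for the classifier, OCB alone, IgG index alone
#' and their sum (a 3-level score), and paired DeLong tests of each marker
#' against the classifier.
#'
#' @param scores classifier probabilities.
#' @param labels binary MS labels aligned with scores.
#' @param ocb,igg logical (or 0/1) marker vectors, NA = not measured.
#' @return object of class \code{marker_comparison}.
#' @export
compare_with_conventional_markers <- function(scores, labels, ocb, igg) {
  pos <- as_binary_labels(labels)
  keep <- !is.na(ocb) & !is.na(igg) & !is.na(scores) & !is.na(pos)
  if (!any(keep)) stop_csf("no participants with both OCB and IgG results")
  s <- scores[keep]; y <- pos[keep]
  ocb <- as.numeric(ocb[keep]); igg <- as.numeric(igg[keep])
  if (length(unique(y)) < 2)
    stop_csf("marker subcohort contains a single class")
  res <- list(
    n_ms = sum(y), n_nonms = sum(!y),
    classifier = auroc(s, y),
    ocb = auroc(ocb, y),
    igg = auroc(igg, y),
    ocb_igg = auroc(ocb + igg, y),
    delong_ocb = delong_paired_test(s, ocb, y),
    delong_igg = delong_paired_test(s, igg, y),
    delong_ocb_igg = delong_paired_test(s, ocb + igg, y))
  class(res) <- "marker_comparison"
  res
}

#' @export
print.marker_comparison <- function(x, ...) {
  cat(sprintf("Classifier vs conventional markers (%d MS, %d non-MS with OCB+IgG)\n",
              x$n_ms, x$n_nonms))
  cat(sprintf("  classifier AUROC %.3f\n", x$classifier$auc))
  cat(sprintf("  OCB %.3f (DeLong p %s), IgG index %.3f (p %s), OCB+IgG %.3f (p %s)\n",
              x$ocb$auc, format_pvalue(x$delong_ocb$p_value),
              x$igg$auc, format_pvalue(x$delong_igg$p_value),
              x$ocb_igg$auc, format_pvalue(x$delong_ocb_igg$p_value)))
  invisible(x)
}

#' List MS participants misclassified by the diagnostic test
#'
#' Every MS participant whose MS probability falls at or below the cutoff,
#' with the ancillary CSF markers that contextualize the miss: OCB and IgG
#' status, sCD27 with a reference flag (against a healthy mean + 2 SD bound)
#' and NFL.
#'
#' @param d standardized per-participant table with columns
#'   \code{participant_id}, \code{diagnosis}, \code{ms_probability} and
#'   (optionally) \code{ocb_positive}, \code{igg_index_elevated},
#'   \code{scd27}, \code{nfl}.
#' @param cutoff probability cutoff.
#' @param scd27_bound upper normal bound for sCD27 (pg/mL); default is the
#'   mean + 2 SD of the generator's healthy lognormal model.
#' @return data.frame, one row per misclassified MS participant (possibly
#'   empty).
#' @export
misclassification_audit <- function(d, cutoff = 0.5, scd27_bound = NULL) {
  if (is.null(scd27_bound)) {
    # healthy lognormal(meanlog, sd) moments for the default generator model
    cfg <- sim_config()
    sdl <- sqrt(cfg$scd27_load^2 + cfg$scd27_sd^2)
    m <- exp(cfg$scd27_meanlog + sdl^2 / 2)
    s <- m * sqrt(exp(sdl^2) - 1)
    scd27_bound <- m + 2 * s
  }
  is_ms <- d$diagnosis %in% c("RRMS", "ProgMS")
  missed <- is_ms & !is.na(d$ms_probability) & d$ms_probability <= cutoff
  out <- data.frame(
    participant_id = d$participant_id[missed],
    diagnosis = d$diagnosis[missed],
    ms_probability = d$ms_probability[missed],
    ocb_positive = if ("ocb_positive" %in% names(d)) d$ocb_positive[missed] else NA,
    igg_index_elevated = if ("igg_index_elevated" %in% names(d))
      d$igg_index_elevated[missed] else NA,
    scd27 = if ("scd27" %in% names(d)) d$scd27[missed] else NA_real_,
    nfl = if ("nfl" %in% names(d)) d$nfl[missed] else NA_real_,
    stringsAsFactors = FALSE
  )
  out$scd27_elevated <- !is.na(out$scd27) & out$scd27 > scd27_bound
  attr(out, "scd27_bound") <- scd27_bound
  out
}

#' Read a per-participant supplementary results table
#'
#' Declarative column mapping: \code{column_map} names the file's columns for
#' each standardized field (defaults below). Mandatory fields are the
#' participant identifier, the diagnosis class and the MS probability;
#' everything else is optional and analyses depending on absent columns are
#' reported unavailable. Diagnosis strings are matched case-insensitively
#' (\code{PPMS}/\code{SPMS}/progressive map to \code{ProgMS}); rows with
#' unparseable classes are rejected with their line numbers.
#'
#' @param path CSV file.
#' @param column_map named character vector mapping standardized fields to
#'   file columns; defaults cover \code{participant_id}, \code{diagnosis},
#'   \code{ms_probability}, \code{progms_probability}, \code{msdss_pred},
#'   \code{center}, \code{age_at_lp}, \code{sex}, \code{baseline_edss},
#'   \code{followup_edss}, \code{interval_years}, \code{ocb_positive},
#'   \code{igg_index_elevated}, \code{scd27}, \code{nfl}.
#' @return standardized data.frame (one row per participant).
#' @export
read_supplementary_results <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_csf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(raw) == 0) stop_csf("empty supplementary table: %s", path)
  default_map <- c(
    participant_id = "participant_id", diagnosis = "diagnosis",
    ms_probability = "ms_probability", progms_probability = "progms_probability",
    msdss_pred = "msdss_pred", center = "center", age_at_lp = "age_at_lp",
    sex = "sex", baseline_edss = "baseline_edss",
    followup_edss = "followup_edss", interval_years = "interval_years",
    ocb_positive = "ocb_positive", igg_index_elevated = "igg_index_elevated",
    scd27 = "scd27", nfl = "nfl")
  map <- default_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  mandatory <- c("participant_id", "diagnosis", "ms_probability")
  absent <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(absent)) {
    stop_csf("missing mandatory column(s) %s (file has: %s)",
             paste(map[absent], collapse = ", "),
             paste(names(raw), collapse = ", "))
  }
  get_col <- function(field, as = identity) {
    col <- map[[field]]
    if (col %in% names(raw)) as(raw[[col]]) else rep(NA, nrow(raw))
  }
  as_flag <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    ifelse(x %in% c("1", "true", "yes", "y", "+", "positive", "abnormal"), TRUE,
           ifelse(x %in% c("0", "false", "no", "n", "-", "negative", "normal"),
                  FALSE, NA))
  }
  dx_raw <- tolower(trimws(as.character(raw[[map[["diagnosis"]]]])))
  dx <- rep(NA_character_, nrow(raw))
  dx[dx_raw %in% c("rrms", "relapsing-remitting ms", "relapsing remitting ms")] <- "RRMS"
  dx[dx_raw %in% c("progms", "ppms", "spms", "progressive ms", "prog ms")] <- "ProgMS"
  dx[dx_raw %in% c("oind")] <- "OIND"
  dx[dx_raw %in% c("nind")] <- "NIND"
  bad <- which(is.na(dx))
  if (length(bad)) {
    warn_csf("rejected %d row(s) with unknown diagnosis label at line(s) %s",
             length(bad), paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  d <- data.frame(
    participant_id = as.character(raw[[map[["participant_id"]]]]),
    diagnosis = dx,
    center = get_col("center"),
    age_at_lp = get_col("age_at_lp", as.numeric),
    sex = get_col("sex", as.character),
    baseline_edss = get_col("baseline_edss", as.numeric),
    followup_edss = get_col("followup_edss", as.numeric),
    interval_years = get_col("interval_years", as.numeric),
    mri_edss_estimate = rep(NA_real_, nrow(raw)),
    ocb_positive = as_flag(get_col("ocb_positive")),
    igg_index_elevated = as_flag(get_col("igg_index_elevated")),
    scd27 = get_col("scd27", as.numeric),
    nfl = get_col("nfl", as.numeric),
    ms_probability = get_col("ms_probability", as.numeric),
    progms_probability = get_col("progms_probability", as.numeric),
    msdss_pred = get_col("msdss_pred", as.numeric),
    stringsAsFactors = FALSE
  )
  d <- d[!is.na(d$diagnosis), , drop = FALSE]
  if (nrow(d) == 0) stop_csf("no parseable rows in %s", path)
  if (any(!is.na(d$ms_probability) &
          (d$ms_probability < 0 | d$ms_probability > 1)))
    stop_csf("MS probabilities outside [0, 1] in %s", path)
  rownames(d) <- NULL
  d
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("CSF molecular-test validation report (%s mode, seed %d)\n",
              x$meta$mode, x$meta$seed))
  cat(sprintf("  cohort: %d participants (%d MS, %d non-MS)\n",
              x$log$n_total, x$log$n_ms, x$log$n_nonms))
  cat("Diagnostic (MS vs non-MS): ")
  print(x$diagnostic$roc)
  cm <- x$diagnostic$confusion
  cat(sprintf("  accuracy %.2f, sensitivity %.2f, specificity %.2f, PPV %.2f, NPV %.2f\n",
              cm$accuracy, cm$sensitivity, cm$specificity, cm$ppv, cm$npv))
  cat(sprintf("  median MS probability %.2f (MS) vs %.2f (non-MS)\n",
              x$diagnostic$median_prob_ms, x$diagnostic$median_prob_nonms))
  if (!is.null(x$diagnostic$per_center)) {
    for (g in names(x$diagnostic$per_center))
      cat(sprintf("  center %s: AUROC %.3f\n", g,
                  x$diagnostic$per_center[[g]]$auc))
  }
  if (!is.null(x$staging)) {
    cat("Staging (RRMS vs progMS): ")
    print(x$staging$roc)
    cat(sprintf("  median progMS probability %.2f (progMS) vs %.2f (RRMS)\n",
                x$staging$median_prob_progms, x$staging$median_prob_rrms))
    if (!is.null(x$staging$multivariate))
      cat(sprintf("  multivariate follow-up model R2 %.2f (n = %d)\n",
                  x$staging$multivariate$r_squared, x$staging$multivariate$n))
  }
  if (!is.null(x$markers)) print(x$markers)
  if (isTRUE(x$prognostic$available)) {
    cat("Prognostic chain (clinician baseline): ")
    cat(sprintf("rho %.2f, R2 %.0f%% -> %.0f%% (gain p %s), n %d\n",
                x$prognostic$clinician$spearman_rho,
                100 * x$prognostic$clinician$r2_base,
                100 * x$prognostic$clinician$r2_augmented,
                format_pvalue(x$prognostic$clinician$p_gain),
                x$prognostic$clinician$n))
    if (!is.null(x$prognostic$mri))
      cat(sprintf("Prognostic chain (MRI baseline): rho %.2f, R2 %.0f%% -> %.0f%% (gain p %s), n %d\n",
                  x$prognostic$mri$spearman_rho, 100 * x$prognostic$mri$r2_base,
                  100 * x$prognostic$mri$r2_augmented,
                  format_pvalue(x$prognostic$mri$p_gain), x$prognostic$mri$n))
  } else {
    cat("Prognostic chain: unavailable (missing EDSS columns or conversion models)\n")
  }
  cat(sprintf("Misclassified MS participants: %d\n", nrow(x$misclassified)))
  invisible(x)
}

# Serialize the report (+ per-participant predictions) to out_dir.
write_report <- function(report, preds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, na = "")
  if (isTRUE(report$prognostic$available) &&
      !is.null(report$prognostic$predictions)) {
    utils::write.csv(report$prognostic$predictions,
                     file.path(out_dir, "prognostic.csv"),
                     row.names = FALSE, na = "")
  }
  roc_json <- function(r) if (is.null(r)) NULL else list(
    auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
    ci = r$ci, p_value = if (!is.null(r$p_value)) format_pvalue(r$p_value))
  reg_json <- function(r) if (is.null(r)) NULL else list(
    spearman_rho = r$spearman_rho, spearman_p = format_pvalue(r$spearman_p),
    r2_base = r$r2_base, r2_augmented = r$r2_augmented,
    p_gain = format_pvalue(r$p_gain), n = r$n)
  j <- list(
    meta = report$meta, log = report$log,
    diagnostic = list(
      roc = roc_json(report$diagnostic$roc),
      per_center = lapply(report$diagnostic$per_center, roc_json),
      confusion = unclass(report$diagnostic$confusion),
      median_prob_ms = report$diagnostic$median_prob_ms,
      median_prob_nonms = report$diagnostic$median_prob_nonms),
    staging = if (!is.null(report$staging)) list(
      roc = roc_json(report$staging$roc),
      median_prob_progms = report$staging$median_prob_progms,
      median_prob_rrms = report$staging$median_prob_rrms,
      multivariate = if (!is.null(report$staging$multivariate)) list(
        r_squared = report$staging$multivariate$r_squared,
        n = report$staging$multivariate$n)),
    markers = if (!is.null(report$markers)) list(
      classifier_auc = report$markers$classifier$auc,
      ocb_auc = report$markers$ocb$auc, igg_auc = report$markers$igg$auc,
      ocb_igg_auc = report$markers$ocb_igg$auc,
      delong_p = list(ocb = format_pvalue(report$markers$delong_ocb$p_value),
                      igg = format_pvalue(report$markers$delong_igg$p_value),
                      ocb_igg = format_pvalue(report$markers$delong_ocb_igg$p_value))),
    prognostic = list(available = report$prognostic$available,
                      clinician = reg_json(report$prognostic$clinician),
                      mri = reg_json(report$prognostic$mri)),
    misclassified = report$misclassified)
  jsonlite::write_json(j, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
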