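# Random-forest diagnostic, staging and severity models.
#
# The probability-producing classifiers mirror the published workflow: a
# random forest trained on log-ratio features emits a probability in [0, 1]
# (fraction of trees voting for the positive class), which is dichotomized at
# a fixed 0.5 cutoff. A regression forest plays the same role for the
# continuous severity score. Forest defaults (500 trees, sqrt(p) features per
# split for classification, p/3 for regression, unlimited depth) follow
# standard random-forest practice; the published models did not specify
# hyperparameters.

#' Train a probability-producing classifier on ratio features
#'
#' @param features feature matrix from [compute_ratio_features()] (rows =
#'   participants); its \code{"cohort_tag"} attribute is recorded so the
#'   validation pipeline can enforce that the model is never evaluated on its
#'   training cohort.
#' @param labels binary class labels aligned with the rows (factor, character
#'   or logical; exactly two observed classes).
#' @param positive the positive class; defaults to the second factor level.
#' @param model_kind free-text tag, e.g. \code{"ms_vs_nonms"}.
#' @param n_trees number of trees (>= 100).
#' @param mtry features tried per split; default \code{floor(sqrt(p))}.
#' @param cutoff probability cutoff used by [classify()] (in (0, 1)).
#' @param stratify if \code{TRUE}, trees are grown on class-balanced
#'   bootstrap samples (off by default: the published models report raw
#'   probabilities without reweighting).
#' @param seed integer seed; training is deterministic given (data, seed).
#' @return object of class \code{csf_model} with the fitted forest, the
#'   training column names, class metadata and an out-of-bag AUROC estimate.
#' @export
train_classifier <- function(features, labels, positive = NULL,
                             model_kind = "ms_vs_nonms",
                             n_trees = 500, mtry = NULL, cutoff = 0.5,
                             stratify = FALSE, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop_csf("features (%d rows) and labels (%d) length mismatch",
             nrow(features), length(labels))
  if (anyNA(features)) stop_csf("features must be complete (no NA)")
  y <- factor(labels)
  y <- droplevels(y)
  if (nlevels(y) != 2)
    stop_csf("labels must have exactly 2 observed classes (got %d)", nlevels(y))
  if (min(table(y)) < 2) stop_csf("need >= 2 samples per class")
  if (n_trees < 100) stop_csf("n_trees must be >= 100")
  if (cutoff <= 0 || cutoff >= 1) stop_csf("cutoff must be in (0, 1)")
  if (is.null(positive)) positive <- levels(y)[2]
  if (!positive %in% levels(y)) stop_csf("positive class '%s' not in labels", positive)
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  samp <- if (stratify) rep(min(table(y)), 2) else nrow(features)
  rf <- with_seed(seed, randomForest::randomForest(
    x = features, y = y, ntree = n_trees, mtry = mtry,
    sampsize = samp, strata = if (stratify) y else NULL
  ))
  oob <- rf$votes[, positive]
  oob_auc <- tryCatch(auroc(oob, y == positive)$auc, error = function(e) NA_real_)
  structure(
    list(forest = rf, model_kind = model_kind,
         panel_name = attr(features, "panel_name"),
         feature_names = colnames(features),
         positive_class = positive, classes = levels(y),
         cutoff = cutoff, seed = as.integer(seed),
         n_samples = nrow(features), class_counts = table(y),
         oob_auroc = oob_auc, oob_probability = unname(oob),
         train_tag = attr(features, "cohort_tag") %||% NA_character_,
         type = "classification"),
    class = "csf_model"
  )
}

#' Train a severity regression forest
#'
#' Regression analogue of [train_classifier()]: predicts a continuous
#' severity score (MS-DSS scale) from severity-panel ratios.
#'
#' @inheritParams train_classifier
#' @param targets numeric severity targets aligned with the feature rows.
#' @return a \code{csf_model} of type \code{"regression"}; out-of-bag
#'   predictions are stored in \code{oob_prediction}.
#' @export
train_severity_regressor <- function(features, targets, n_trees = 500,
                                     mtry = NULL, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != length(targets))
    stop_csf("features and targets length mismatch")
  if (nrow(features) < 30)
    stop_csf("severity regressor needs >= 30 training samples (got %d)",
             nrow(features))
  if (anyNA(features) || anyNA(targets)) stop_csf("inputs must be complete")
  if (stats::sd(targets) == 0) stop_csf("constant severity target")
  if (n_trees < 100) stop_csf("n_trees must be >= 100")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(features) / 3))
  rf <- with_seed(seed, randomForest::randomForest(
    x = features, y = as.numeric(targets), ntree = n_trees, mtry = mtry
  ))
  structure(
    list(forest = rf, model_kind = "severity_regression",
         panel_name = attr(features, "panel_name"),
         feature_names = colnames(features),
         positive_class = NULL, classes = NULL, cutoff = NA_real_,
         seed = as.integer(seed), n_samples = nrow(features),
         class_counts = NULL,
         oob_auroc = NA_real_, oob_prediction = unname(rf$predicted),
         train_tag = attr(features, "cohort_tag") %||% NA_character_,
         type = "regression"),
    class = "csf_model"
  )
}

#' Predict probabilities (or severity scores) for new profiles
#'
#' Feature columns must match the training columns exactly, by name and
#' order. For classification models the probability is the fraction of trees
#' voting for the positive class; for regression models the forest mean is
#' returned as \code{prediction}.
#'
#' @param model a \code{csf_model}.
#' @param features feature matrix with the training columns.
#' @param allow_training_data if \code{FALSE} (default), predicting on a
#'   feature matrix carrying the model's own training provenance tag is an
#'   error — external-validation discipline.
#' @return data.frame with \code{participant_id} and \code{probability}
#'   (classification) or \code{prediction} (regression), one row per feature
#'   row; empty input gives an empty data.frame.
#' @export
predict_probabilities <- function(model, features, allow_training_data = FALSE) {
  stopifnot(inherits(model, "csf_model"))
  features <- as.matrix(features)
  if (!identical(colnames(features), model$feature_names)) {
    extra <- setdiff(colnames(features), model$feature_names)
    miss <- setdiff(model$feature_names, colnames(features))
    stop_csf(paste0(
      "feature columns do not match training columns (names and order are checked).",
      if (length(miss)) sprintf(" Missing: %s.", paste(utils::head(miss, 5), collapse = ", ")) else "",
      if (length(extra)) sprintf(" Unexpected: %s.", paste(utils::head(extra, 5), collapse = ", ")) else "",
      " Reorder with features[, model$feature_names]."))
  }
  tag <- attr(features, "cohort_tag")
  if (!allow_training_data && !is.null(tag) && !is.na(model$train_tag) &&
      identical(tag, model$train_tag)) {
    stop_csf(paste("features carry the model's training provenance tag (%s);",
                   "evaluation must use an external cohort",
                   "(use the stored out-of-bag estimates for training data)"),
             tag)
  }
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  if (nrow(features) == 0) {
    return(if (model$type == "classification")
      data.frame(participant_id = character(0), probability = numeric(0))
      else data.frame(participant_id = character(0), prediction = numeric(0)))
  }
  if (model$type == "classification") {
    pr <- stats::predict(model$forest, features, type = "vote", norm.votes = TRUE)
    data.frame(participant_id = ids,
               probability = unname(pr[, model$positive_class]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(participant_id = ids,
               prediction = unname(stats::predict(model$forest, features)),
               stringsAsFactors = FALSE)
  }
}

#' @export
predict.csf_model <- function(object, newdata, ...) {
  predict_probabilities(object, newdata, ...)
}

#' Dichotomize a probability at the model cutoff
#'
#' The positive class is assigned iff \code{probability > cutoff}; a
#' probability exactly at the cutoff goes to the negative class (conservative
#' tie rule, documented).
#'
#' @param probability numeric vector of probabilities in [0, 1] (no NA).
#' @param cutoff probability cutoff, default 0.5.
#' @param positive,negative class labels to return.
#' @return character vector of predicted classes.
#' @export
#' @examples
#' classify(c(0.95, 0.5, 0.47))  # "positive" "negative" "negative"
classify <- function(probability, cutoff = 0.5,
                     positive = "positive", negative = "negative") {
  if (anyNA(probability)) stop_csf("missing probability in classify()")
  if (any(probability < 0 | probability > 1))
    stop_csf("probabilities must lie in [0, 1]")
  ifelse(probability > cutoff, positive, negative)
}

#' @export
print.csf_model <- function(x, ...) {
  if (x$type == "classification") {
    cat(sprintf("CSF random-forest classifier [%s], panel '%s'\n",
                x$model_kind, x$panel_name %||% "?"))
    cat(sprintf("  %d trees, %d features, n = %d (%s), cutoff %.2f\n",
                x$forest$ntree, length(x$feature_names), x$n_samples,
                paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                      collapse = ", "), x$cutoff))
    cat(sprintf("  out-of-bag AUROC %.3f (positive class '%s')\n",
                x$oob_auroc, x$positive_class))
  } else {
    cat(sprintf("CSF random-forest severity regressor, panel '%s'\n",
                x$panel_name %||% "?"))
    cat(sprintf("  %d trees, %d features, n = %d, OOB %% variance explained %.1f\n",
                x$forest$ntree, length(x$feature_names), x$n_samples,
                100 * x$forest$rsq[x$forest$ntree]))
  }
  invisible(x)
}
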