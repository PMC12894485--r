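# ROC inference from first principles.
#
# AUROC is the Mann-Whitney estimator (ties credited 1/2), equal to the
# trapezoidal area under the empirical ROC curve. Confidence intervals come
# from a stratified percentile bootstrap; significance against AUC = 0.5 uses
# the Mann-Whitney U null distribution after Mason & Graham (normal
# approximation with tie correction, exact enumeration for small samples);
# paired model comparisons use DeLong's placement-value variance.

# Coerce labels to logical (TRUE = positive). Accepts logical, 0/1 numeric,
# factor or character with an explicit positive class.
as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  f <- factor(labels)
  if (nlevels(f) != 2)
    stop_csf("labels must be binary (got %d classes)", nlevels(f))
  if (is.null(positive)) positive <- levels(f)[2]
  f == positive
}

# Bare AUROC via midranks; the hot path for bootstrap and simulation loops.
auroc_value <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- length(pos) - n1
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Over all positive x negative pairs, a pair scores 1 when the positive
#' outranks the negative and 1/2 on a tie; the average equals the trapezoidal
#' area under the empirical ROC curve. Ties arise routinely here because
#' forest vote fractions are discrete.
#'
#' @param scores numeric vector.
#' @param labels binary labels (logical, 0/1, or two-level factor).
#' @param positive positive class when labels are a factor/character.
#' @return object of class \code{roc_result} with \code{auc}, \code{n_pos},
#'   \code{n_neg}; confidence interval and p-value slots are filled by
#'   [bootstrap_auc_ci()] and [mason_graham_p()].
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0, 0))$auc  # 8/9
auroc <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  if (length(scores) != length(pos)) stop_csf("scores/labels length mismatch")
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 1 || n0 < 1)
    stop_csf("need at least one positive and one negative (got %d/%d)", n1, n0)
  structure(
    list(auc = auroc_value(scores, pos), n_pos = n1, n_neg = n0,
         ci = NULL, p_value = NULL, method_tag = "mann-whitney"),
    class = "roc_result"
  )
}

#' Stratified bootstrap confidence interval for the AUROC
#'
#' Positives and negatives are resampled separately with replacement (so no
#' resample is degenerate), and the percentile interval of the resampled AUCs
#' is reported; a bias-corrected accelerated (BCa) interval is available via
#' \code{type = "bca"}.
#'
#' @inheritParams auroc
#' @param n_boot number of bootstrap replicates (default 2000; a warning is
#'   issued below 100).
#' @param level confidence level.
#' @param seed integer seed; the interval is reproducible given (data, seed).
#' @param type \code{"percentile"} (default) or \code{"bca"}.
#' @return a \code{roc_result} whose \code{ci} holds \code{level},
#'   \code{lower}, \code{upper}, \code{n_boot}, \code{seed}.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = 1L, positive = NULL,
                             type = c("percentile", "bca")) {
  type <- match.arg(type)
  res <- auroc(scores, labels, positive)
  pos <- as_binary_labels(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (res$n_pos < 2 || res$n_neg < 2)
    stop_csf("bootstrap CI needs >= 2 per class")
  if (n_boot < 100) warn_csf("n_boot = %d is small; interval will be unstable", n_boot)
  ip <- which(pos); im <- which(!pos)
  sp <- scores[ip]; sm <- scores[im]
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bs <- c(sp[sample.int(length(sp), replace = TRUE)],
              sm[sample.int(length(sm), replace = TRUE)])
      auroc_value(bs, c(rep(TRUE, length(sp)), rep(FALSE, length(sm))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  if (type == "percentile") {
    qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  } else {
    # BCa: bias correction from the fraction of replicates below the point
    # estimate, acceleration from a jackknife over observations
    z0 <- stats::qnorm(clamp(mean(boot < res$auc) + 0.5 * mean(boot == res$auc),
                             1e-6, 1 - 1e-6))
    jk <- vapply(seq_along(scores), function(i) {
      auroc_value(scores[-i], pos[-i])
    }, numeric(1))
    jm <- mean(jk)
    num <- sum((jm - jk)^3); den <- 6 * (sum((jm - jk)^2))^1.5
    a <- if (den == 0) 0 else num / den
    zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
    p1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    qs <- stats::quantile(boot, c(p1, p2), names = FALSE, type = 7)
  }
  res$ci <- list(level = level, lower = min(qs[1], res$auc),
                 upper = max(qs[2], res$auc), n_boot = n_boot,
                 seed = as.integer(seed))
  res$method_tag <- paste0("mann-whitney+", type, "-bootstrap")
  res
}

# Null moments of the rank sum of the positives, with tie correction.
rank_sum_null <- function(scores, n1) {
  n <- length(scores); n0 <- n - n1
  mu <- n1 * (n + 1) / 2
  t <- table(scores)
  tie_term <- sum(t^3 - t) / ((n) * (n - 1))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
  list(mu = mu, sigma = sqrt(sigma2))
}

#' Significance of an AUROC against 0.5 (Mason-Graham)
#'
#' Tests H0: AUC = 0.5 using the Mann-Whitney U statistic under label
#' exchangeability. Small samples (pooled n <= 12, or \code{exact = TRUE})
#' use exact enumeration of all label assignments; otherwise the exact
#' Mann-Whitney null distribution when the scores are tie-free, and a normal
#' approximation with tie and continuity corrections in the presence of
#' ties. Reported one-sided toward AUC > 0.5 by default.
#'
#' @inheritParams auroc
#' @param alternative \code{"greater"} (one-sided, default) or
#'   \code{"two.sided"}.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) enumeration;
#'   \code{NULL} decides by sample size.
#' @return p-value in (0, 1].
#' @export
mason_graham_p <- function(scores, labels, positive = NULL,
                           alternative = c("greater", "two.sided"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  pos <- as_binary_labels(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n <- length(scores); n1 <- sum(pos); n0 <- n - n1
  if (n1 < 1 || n0 < 1) stop_csf("need both classes")
  r <- rank(scores, ties.method = "average")
  w_obs <- sum(r[pos])
  use_exact <- exact %||% (n <= 12)
  if (use_exact) {
    if (choose(n, n1) > 2e5)
      stop_csf("exact enumeration infeasible for choose(%d, %d) assignments", n, n1)
    combs <- utils::combn(n, n1)
    w_perm <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-9
    p_greater <- mean(w_perm >= w_obs - eps)
    if (alternative == "greater") return(p_greater)
    p_less <- mean(w_perm <= w_obs + eps)
    return(min(1, 2 * min(p_greater, p_less)))
  }
  if (!anyDuplicated(scores) && n1 < 50 && n0 < 50) {
    # tie-free: exact Mann-Whitney null distribution
    u <- w_obs - n1 * (n1 + 1) / 2
    p_greater <- stats::pwilcox(u - 1, n1, n0, lower.tail = FALSE)
    if (alternative == "greater") return(p_greater)
    p_less <- stats::pwilcox(u, n1, n0)
    return(min(1, 2 * min(p_greater, p_less)))
  }
  nul <- rank_sum_null(scores, n1)
  z <- (w_obs - nul$mu - 0.5) / nul$sigma
  if (alternative == "greater") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    zc <- (abs(w_obs - nul$mu) - 0.5) / nul$sigma
    min(1, 2 * stats::pnorm(zc, lower.tail = FALSE))
  }
}

# DeLong placement values: for each positive, the mean win indicator against
# all negatives (and vice versa).
placements <- function(scores, pos) {
  sp <- scores[pos]; sm <- scores[!pos]
  v10 <- vapply(sp, function(x) mean((x > sm) + 0.5 * (x == sm)), numeric(1))
  v01 <- vapply(sm, function(y) mean((sp > y) + 0.5 * (sp == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUCs of two score vectors evaluated on the same participants
#' and labels, with the covariance of the two estimators obtained from
#' per-observation placement values (DeLong, DeLong & Clarke-Pearson).
#' Two-sided normal p-value for H0: AUC_a = AUC_b.
#'
#' @param scores_a,scores_b aligned score vectors.
#' @inheritParams auroc
#' @return object of class \code{delong_test}: list with \code{auc_a},
#'   \code{auc_b}, \code{z}, \code{p_value}, \code{var_diff}.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_csf("scores_a, scores_b and labels must be aligned (same length)")
  pos <- as_binary_labels(labels, positive)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(pos)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2 || n0 < 2) stop_csf("DeLong test needs >= 2 per class")
  pa <- placements(scores_a, pos); pb <- placements(scores_b, pos)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (var_diff <= 0 || abs(auc_a - auc_b) < 1e-12) {
    z <- 0; p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, z = z, p_value = p,
                 var_diff = max(var_diff, 0), n_pos = n1, n_neg = n0),
            class = "delong_test")
}

#' Confusion metrics at a probability cutoff
#'
#' Counts follow the [classify()] tie rule (score > cutoff is called
#' positive). Positive/negative predictive values are reported as \code{NA}
#' with a warning when their denominator is empty.
#'
#' @inheritParams auroc
#' @param cutoff score cutoff, default 0.5.
#' @return object of class \code{confusion_metrics}: counts \code{tp},
#'   \code{fp}, \code{tn}, \code{fn} and rates \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}, \code{accuracy}.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 0.5, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (!any(pos) || all(pos)) stop_csf("both classes must be present")
  called <- scores > cutoff
  tp <- sum(called & pos); fp <- sum(called & !pos)
  tn <- sum(!called & !pos); fn <- sum(!called & pos)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn_csf("%s undefined (empty denominator); reported as NA", what)
      NA_real_
    } else num / den
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         ppv = safe_div(tp, tp + fp, "PPV"),
         npv = safe_div(tn, tn + fn, "NPV"),
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         cutoff = cutoff),
    class = "confusion_metrics"
  )
}

#' Per-group AUROCs (e.g. per center)
#'
#' @inheritParams auroc
#' @param groups grouping vector aligned with scores; groups missing a class
#'   are skipped with a warning.
#' @return list with \code{pooled} (a \code{roc_result}) and \code{by_group}
#'   (named list of \code{roc_result}, skipped groups absent).
#' @export
auroc_by_group <- function(scores, labels, groups, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  pooled <- auroc(scores, pos)
  by_group <- list()
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    if (length(unique(pos[idx])) < 2) {
      warn_csf("group '%s' lacks one of the classes; skipped", g)
      next
    }
    by_group[[as.character(g)]] <- auroc(scores[idx], pos[idx])
  }
  list(pooled = pooled, by_group = by_group)
}

#' Empirical ROC curve coordinates
#'
#' Sensitivity vs 1 - specificity at descending score thresholds, including
#' the (0,0) and (1,1) anchors.
#'
#' @inheritParams auroc
#' @return data.frame with \code{threshold}, \code{sensitivity},
#'   \code{specificity}.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!pos] < t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%d positives, %d negatives)", x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$ci))
    cat(sprintf(" [%.0f%% CI %.3f-%.3f, %d bootstraps]",
                100 * x$ci$level, x$ci$lower, x$ci$upper, x$ci$n_boot))
  if (!is.null(x$p_value)) cat(sprintf(", p = %.2g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUC %.3f vs %.3f, z = %.2f, p = %.2g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion at cutoff %.2f: TP %d FP %d TN %d FN %d\n",
              x$cutoff, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.2f, specificity %.2f, PPV %.2f, NPV %.2f, accuracy %.2f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  invisible(x)
}
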