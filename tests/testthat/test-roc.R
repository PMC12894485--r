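# ROC inference: Mann-Whitney AUROC, bootstrap CI, Mason-Graham significance,
# DeLong paired comparison, confusion metrics, grouped AUROCs. Cross-checked
# against brute-force oracles and, where available, the pROC package.

test_that("auroc equals brute-force pair counting, with ties credited 1/2", {
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auroc(s, y)$auc, 8 / 9)
  expect_equal(auroc(rep(1, 6), y)$auc, 0.5)           # total ties
  expect_equal(auroc(-s, y)$auc, 1 - auroc(s, y)$auc)  # antisymmetry
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(auroc(scores, pos)$auc, brute_force_auc(scores, pos))
  }
  # invariance under strictly increasing transforms
  set.seed(102)
  scores <- rnorm(40); pos <- rep(c(TRUE, FALSE), 20)
  expect_equal(auroc(exp(scores), pos)$auc, auroc(scores, pos)$auc)
  expect_error(auroc(1:5, rep(TRUE, 5)), "at least one")
})

test_that("auroc agrees with pROC and with trapezoidal curve integration", {
  skip_if_not_installed("pROC")
  set.seed(103)
  scores <- round(rnorm(60), 1); pos <- runif(60) < 0.4
  ours <- auroc(scores, pos)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
  cur <- roc_curve(scores, pos)
  fpr <- 1 - cur$specificity
  trap <- sum(diff(fpr) * (head(cur$sensitivity, -1) + tail(cur$sensitivity, -1)) / 2)
  expect_equal(trap, ours)
  expect_equal(cur$sensitivity[1], 0)
  expect_equal(tail(cur$sensitivity, 1), 1)
})

test_that("stratified bootstrap CI is seeded, ordered and sane at the edges", {
  set.seed(104)
  scores <- c(rnorm(30, 1), rnorm(40))
  pos <- rep(c(TRUE, FALSE), c(30, 40))
  r1 <- bootstrap_auc_ci(scores, pos, n_boot = 500, seed = 9)
  r2 <- bootstrap_auc_ci(scores, pos, n_boot = 500, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci$lower, r1$auc)
  expect_gte(r1$ci$upper, r1$auc)
  # perfect separation: upper limit 1
  sep <- bootstrap_auc_ci(c(2, 3, 4, 0, -1, -2), rep(c(TRUE, FALSE), each = 3),
                          n_boot = 200, seed = 1)
  expect_equal(sep$ci$upper, 1)
  expect_warning(bootstrap_auc_ci(scores, pos, n_boot = 50, seed = 1), "small")
  # BCa variant runs and brackets the estimate
  bca <- bootstrap_auc_ci(scores, pos, n_boot = 500, seed = 9, type = "bca")
  expect_lte(bca$ci$lower, bca$auc)
})

test_that("Mason-Graham p is exact for small n and sane under the null", {
  # perfect separation with 2 vs 2: exact p = 1/choose(4,2) = 1/6
  expect_equal(mason_graham_p(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1 / 6)
  # interleaved scores (AUC = 0.5): p >= 0.5
  expect_gte(mason_graham_p(1:10, rep(c(1, 0), 5)), 0.5)
  # exact mode equals the independent enumeration oracle, with ties
  set.seed(105)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    scores <- sample(1:5, n, replace = TRUE)
    pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(mason_graham_p(scores, pos, exact = TRUE),
                 enumeration_p_oracle(scores, pos))
  }
  # normal approximation close to exact at n = 12
  set.seed(106)
  for (i in 1:10) {
    scores <- rnorm(12)
    pos <- c(rep(TRUE, 5), rep(FALSE, 7))[sample.int(12)]
    expect_lt(abs(mason_graham_p(scores, pos, exact = TRUE) -
                    mason_graham_p(scores, pos, exact = FALSE)), 0.02)
  }
  expect_error(mason_graham_p(1:4, rep(1, 4)), "both classes")
})

test_that("DeLong test has the identity, rank-invariance and symmetry properties", {
  set.seed(107)
  scores <- rnorm(40); pos <- rep(c(TRUE, FALSE), 20)
  same <- delong_paired_test(scores, scores, pos)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_paired_test(scores, exp(scores) + 2, pos)
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$p_value, 1)
  other <- rnorm(40) + pos
  ab <- delong_paired_test(scores, other, pos)
  ba <- delong_paired_test(other, scores, pos)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_gte(ab$var_diff, 0)
  expect_error(delong_paired_test(scores, other[-1], pos), "aligned")
})

test_that("DeLong agrees with pROC's paired implementation", {
  skip_if_not_installed("pROC")
  set.seed(108)
  pos <- rep(c(TRUE, FALSE), c(35, 45))
  a <- rnorm(80) + pos * 1.2
  b <- 0.5 * a + rnorm(80) + pos * 0.6
  ours <- delong_paired_test(a, b, pos)
  theirs <- pROC::roc.test(pROC::roc(pos, a, quiet = TRUE, direction = "<"),
                           pROC::roc(pos, b, quiet = TRUE, direction = "<"),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-9)
  expect_equal(abs(ours$z), abs(unname(theirs$statistic)), tolerance = 1e-9)
})

test_that("confusion metrics satisfy their arithmetic identities", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.55)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  cm <- confusion_at_cutoff(scores, pos, cutoff = 0.5)
  expect_equal(cm$tp + cm$fn, sum(pos))
  expect_equal(cm$tn + cm$fp, sum(!pos))
  expect_equal(cm$sensitivity, cm$tp / (cm$tp + cm$fn))
  expect_equal(cm$specificity, cm$tn / (cm$tn + cm$fp))
  expect_equal(cm$ppv, cm$tp / (cm$tp + cm$fp))
  expect_equal(cm$npv, cm$tn / (cm$tn + cm$fn))
  expect_equal(cm$accuracy, (cm$tp + cm$tn) / 6)
  # all called positive at cutoff 0: sensitivity 1, specificity 0
  expect_warning(all_pos <- confusion_at_cutoff(scores, pos, cutoff = 0), "NPV")
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_warning(npv <- confusion_at_cutoff(scores, pos, cutoff = 1)$ppv, "PPV")
  # perfectly separated scores
  sep <- confusion_at_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_error(confusion_at_cutoff(scores, rep(TRUE, 6)), "both classes")
})

test_that("grouped AUROCs match pooled behaviour and skip degenerate groups", {
  set.seed(109)
  scores <- rnorm(40); pos <- rep(c(TRUE, FALSE), 20)
  one <- auroc_by_group(scores, pos, rep(1, 40))
  expect_equal(one$by_group[["1"]]$auc, one$pooled$auc)
  two <- auroc_by_group(c(scores, scores), c(pos, pos), rep(1:2, each = 40))
  expect_equal(two$by_group[["1"]]$auc, two$by_group[["2"]]$auc)
  grp <- c(rep(1, 38), 2, 2)
  expect_warning(res <- auroc_by_group(scores, pos, ifelse(pos, 1, grp)),
                 "skipped")
})

test_that("per-center AUROC ordering follows center effect sizes", {
  # three centers with increasing diagnostic effect: AUC order must match
  rank_hits <- vapply(1:20, function(s) {
    set.seed(s + 900)
    eff <- c(0.5, 1.5, 3)
    scores <- unlist(lapply(eff, function(e) rnorm(40) + rep(c(e, 0), 20)))
    pos <- rep(rep(c(TRUE, FALSE), 20), 3)
    centers <- rep(1:3, each = 40)
    res <- auroc_by_group(scores, pos, centers)
    aucs <- vapply(res$by_group, `[[`, numeric(1), "auc")
    all(diff(aucs) > 0)
  }, logical(1))
  expect_gt(mean(rank_hits), 0.8)
})
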