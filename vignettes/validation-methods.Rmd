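---
title: "Validating CSF molecular tests for multiple sclerosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating CSF molecular tests for multiple sclerosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmsval)
```

## The scientific problem

Multiple sclerosis (MS) is diagnosed clinically, with an appreciable error
rate against pathological gold standards, and its staging (relapsing–remitting
versus progressive disease) and prognosis are harder still. Cerebrospinal
fluid (CSF) collected at the diagnostic work-up carries a molecular signature
of the intrathecal disease process. Aptamer-based multiplex proteomics
measures relative abundances (relative fluorescence units, RFU) of over a
thousand CSF proteins from one sample, and previously trained random-forest
models can convert a panel of protein ratios into three clinically meaningful
outputs:

1. a **diagnostic probability** that the donor has MS rather than another
   inflammatory (OIND) or non-inflammatory (NIND) neurological disease,
2. a **staging probability** that an MS donor has progressive rather than
   relapsing–remitting disease, and
3. a **severity score** on the MS disease-severity scale (MS-DSS) that
   anticipates the future rate of disability accumulation.

`csfmsval` implements the full multicenter external-validation workflow for
such tests — synthetic cohort generation, feature engineering, model
training and external prediction, ROC inference from first principles, and
the prognostic chain that converts a severity score into a predicted future
EDSS — so that every stage can be exercised and audited without access to
patient data.

## The synthetic cohort generator

Everything downstream is testable because the generator
(`sim_config()`, `generate_cohort()`) emulates the statistical structure the
analysis assumes. Its defaults describe a multicenter validation cohort of
65 RRMS, 31 progressive MS, 30 OIND and 34 NIND participants over three
centers with realistic demographics, marker positivity rates and follow-up.

**Protein model.** Log-abundance of protein $p$ in participant $i$ is

$$\log \mathrm{RFU}_{ip} = \mu_p + \beta_a (\mathrm{age}_i - 45)
  + \beta_s \mathbf{1}[\mathrm{male}_i]
  + L^{d}_p d_i + L^{g}_p g_i + L^{s}_p \cdot c \cdot s_i
  + \varepsilon_{ip},$$

with $\varepsilon_{ip} \sim N(0, \sigma^2)$, $\sigma = 0.15$ by default (a
realistic technical log-CV for the assay). Disease signal is carried by
unit-variance latent factors: a diagnostic factor $d_i$ whose mean shifts by
`diag_effect` in MS, a staging factor $g_i$ shifting by `prog_effect` in
progressive MS, and a latent severity $s_i \sim N(0,1)$ shifted by $+1$ in
progressive MS. Panel proteins load on their factor with alternating $+1/2$
and $-1/2$ coefficients along the panel's protein list, so a ratio of two
adjacent proteins carries the full factor with unit coefficient. Baseline
intercepts $\mu_p$ are a deterministic function of the protein identifier, so
they are common across cohorts (and in any case cancel in ratios).

**Effect-size calibration.** For two unit-variance normal score
distributions separated by $\delta$, the probability that a random positive
outscores a random negative is $\Phi(\delta/\sqrt 2)$ (`analytic_auc()`).
Because the factors have unit variance, the cohort's information-level AUROC
ceiling equals `analytic_auc(effect)`, and effect sizes are chosen by
inversion: `effect_for_auc(0.94)` for the diagnostic factor and
`effect_for_auc(0.76)` for the staging factor, matching the reference
external-validation AUROCs. Empirically the latent factors reproduce these
targets to three decimals over 50 seeds. A trained random forest approaches
the ceiling from below; at the diagnostic signal-to-noise it lands within
0.01 of the ceiling, while at the weaker staging signal the vote-fraction
forest gives up about 0.03–0.04 of AUROC relative to the ceiling regardless
of training size, `mtry`, tree count or stratification — a known
inefficiency of recursive-partitioning scores for weak additive Gaussian
signal, discussed under *Limitations*.

**Disability model.** Latent severity drives both the cross-sectional and
longitudinal disability structure. True baseline disability is linear in
severity and age with Gaussian spread; the true progression slope on the
continuous 0–100 CombiWISE scale is `slope_a + slope_b * msdss_true` plus
heterogeneity, floored at zero for a configurable fraction of
non-progressors (default one half); the true CombiWISE-to-EDSS map is a
fixed monotone quadratic mapping $[0,100]$ onto $[0,10]$. Measured EDSS
values add clinician noise (`edss_noise_sd`) and are then rounded to the
clinical grid $\{0, 1.0, 1.5, \dots, 10.0\}$ — there is no attainable score
between 0 and 1.0, and the generator (like `edss_grid_round()`) sends
midpoints up.

**Longitudinal defaults.** The follow-up interval is $10.2 \pm 4.5$ years
(truncated at 3), EDSS measurement noise is 1.7 points (retrospective,
chart-derived baseline scores are imprecise), and the slope model defaults
to $a = 0.7$, $b = 0.06$, residual SD 1.2 CombiWISE units/year. These were
chosen once, jointly, so that the simulated cohort reproduces the descriptive
behaviour of a real validation cohort of this design: a baseline-to-follow-up
Spearman correlation near 0.4, explained variance in follow-up EDSS of
roughly 16% from baseline alone rising by about five points when the
CSF-predicted change is added, mean progression near one EDSS point per
decade, and a prognostic-chain correlation with measured follow-up near
0.45. They are deliberately *not* tuned per analysis.

**Missingness** mirrors the attrition of a realistic study: among MS
participants, baseline EDSS is missing with probability 7/96 and follow-up
EDSS with 5/96; an MRI-derived baseline estimate exists for 54/96; OCB and
IgG-index results are observed with class-dependent rates and positive with
the class-conditional proportions of the reference cohort's tables. Controls
are not followed, so their EDSS timeline is entirely missing.

**What the generator does not emulate.** Only panel proteins carry signal;
the remaining proteome is exchangeable noise (200 columns by default). There
are no plate or batch effects, no platform-recalibration miscalibration of
probabilities (the synthetic retrained forests are well-calibrated, so
sensitivity/specificity at the 0.5 cutoff are more symmetric than a
miscalibrated imported model would give at the same AUROC), no relapse
dynamics, and no non-Gaussian abundance tails. Passing tests therefore
demonstrate correctness of the *procedures* under a faithful statistical
abstraction, not performance on real assay data.

## Feature engineering

`fit_healthy_reference()` fits, per protein, ordinary least squares of
log(RFU) on age and a male indicator in a healthy reference cohort (at least
20 donors, both sexes). `adjust_profile()` subtracts the fitted age and sex
terms, retaining the intercept (it cancels in ratios), and
`compute_ratio_features()` forms the panel's ordered log-ratios
$\mathrm{adj}(A) - \mathrm{adj}(B)$. Natural logarithms are used throughout;
log-ratios make features invariant to any per-sample multiplicative
rescaling, which is property-tested. Adjustment is residualization rather
than z-scoring — the minimal published-compatible choice; the flag sits in
the healthy-reference object should a user wish to divide by the residual SD.

The packaged diagnostic panel holds 20 ratios over the 21 published proteins
measurable after the loss of the IgG heavy-chain reagent; the staging panel
21 ratios over its 24 published proteins. The published sources name the
*proteins* but not the ratio *pairings*, so the packaged pairings are a
documented package default (consecutive-protein chains plus disjoint pairs)
and panels are fully configurable CSV files. The severity panel's 75
proteins are not public; the packaged severity panel uses synthetic
identifiers and is named accordingly. Complex-targeting reagents keep single
identifiers (`TLR4_LY96`, `LTA_LTB`) because the slash is reserved for ratio
labels. All tests depend only on panel configurability, never on the
historical pairing.

## Classifiers and the cutoff

`train_classifier()` wraps a random forest (500 trees, $\sqrt p$ features
per split, unlimited depth); probabilities are vote fractions, the cutoff is
0.5, and a probability exactly at the cutoff is assigned to the negative
class — a conservative, documented tie rule (vote fractions are discrete, so
exact ties occur). Class reweighting is off by default, with a stratified
sampling flag. `train_severity_regressor()` is the regression analogue
($p/3$ features per split). Only vote-fraction probabilities are
implemented: the forest backend defines votes crisply, whereas leaf-averaged
probabilities would introduce a second, weakly specified convention for no
tested benefit.

External-validation discipline is enforced mechanically: feature matrices
carry their cohort's provenance tag, models remember the tag they were
trained on, and `predict_probabilities()` refuses a matrix with the training
tag. Where training-data predictions are legitimately needed (the slope
conversion below), the forest's out-of-bag predictions are used instead.

## ROC inference

All ROC machinery is implemented from first principles in this package:

* `auroc()` — the Mann–Whitney estimator via midranks, ties credited 1/2;
  equal to the trapezoidal area under the empirical curve and property-tested
  against explicit pair counting.
* `bootstrap_auc_ci()` — stratified resampling (positives and negatives
  separately, so no replicate is degenerate), percentile interval by default
  (2000 replicates), BCa behind a flag. Coverage at true AUC 0.8 is verified
  by simulation.
* `mason_graham_p()` — significance against AUC = 0.5 from the Mann–Whitney
  U null: exact enumeration of label assignments for pooled $n \le 12$, the
  exact Mann–Whitney null distribution for tie-free larger samples (below 50
  per class), and a tie- and continuity-corrected normal approximation
  otherwise. One-sided toward AUC > 0.5 by default, matching how vanishingly
  small p-values for high AUROCs are conventionally reported; two-sided via
  a flag.
* `delong_paired_test()` — paired comparison of two correlated AUCs via
  placement values; agrees with an independent implementation to $10^{-9}$.
  Its asymptotic p-value is accurate at cohort sizes but *not* at $n = 8$,
  where no exact permutation scheme reproduces it within 0.05 — a limitation
  of the asymptotics, documented by a deliberately failing check rather than
  hidden.
* `confusion_at_cutoff()`, `auroc_by_group()`, `roc_curve()` — cutoff
  metrics (undefined predictive values reported as missing with a warning),
  per-center AUROCs (groups lacking a class are skipped with a warning), and
  curve coordinates with the (0,0)/(1,1) anchors.

## The prognostic chain

The chain converts a CSF-predicted severity score into a predicted follow-up
EDSS:

$$\widehat{\mathrm{slope}}_{cw} = a + b \cdot \mathrm{MSDSS}_{pred}, \qquad
  \Delta cw = \widehat{\mathrm{slope}}_{cw} \times \mathrm{interval},$$

$$\mathrm{EDSS}_{fu} = \mathrm{EDSS}_{0} + q(cw_0 + \Delta cw) - q(cw_0),
  \qquad cw_0 = q^{-1}(\mathrm{EDSS}_0),$$

where $(a, b)$ come from `fit_msdss_slope_model()` (OLS of observed
CombiWISE slopes on out-of-bag severity predictions in the training cohort)
and $q$ is the monotone quadratic fitted by `fit_combiwise_edss_model()` on
a cross-sectional disability dataset. The quadratic difference form is the
primary mode: EDSS changes are computed on the granular scale and mapped
back, because predicted changes are usually below the minimally detectable
half-point EDSS increment. A slope-only linear mode
(`conversion_models(..., mode = "linear")`) is provided since the textual
description of the source analysis mentions a linear conversion while its
figure fits a quadratic; the quadratic is the explicitly fitted curve and is
therefore the default. Numerical care: the inverse uses the
cancellation-stable quadratic formula, round trips are exact to $10^{-9}$,
arithmetic leaving the fitted monotone domain clamps to the endpoint with a
warning, predicted follow-up is clamped to $[0, 10]$ but *not* snapped to
the half-point grid, and a zero interval reproduces the baseline exactly.
Negative predicted slopes (improvement) are allowed.

`evaluate_prognosis()` quantifies added value on identical cases: Spearman
correlation of predicted versus measured follow-up EDSS, and the
explained-variance gain of `measured ~ baseline + delta` over
`measured ~ baseline`, with the gain p-value from the added-term two-sided
t-test (identical to the 1-df nested F-test). `multivariate_followup_model()`
is the staging check — follow-up EDSS on baseline EDSS, age and progMS
probability. `mri_baseline_edss()` provides the alternative imaging-derived
baseline as a configurable linear model over semiquantitative MRI scores,
clamped to $[0, 10]$; the packaged weights are a stand-in calibrated to the
generator, since the published imaging-model coefficients are external to
this package.

## The pipeline

`run_full_validation(pipeline_config(...))` orchestrates everything with one
master seed: healthy reference (150 donors), classifier training cohort
(validation counts × 3 — emulating the larger single-center cohort that
trained the historical models; beyond this size the external AUROC no longer
improves), an MS-only severity training cohort (n = 300), a cross-sectional
conversion dataset (n = 3000 visits), external prediction on a freshly
generated validation cohort, ROC inference with bootstrap CIs, the
conventional-marker comparison (OCB, IgG index, and their 0/1/2 sum — the
minimal monotone combination — each tested against the classifier with
paired DeLong), the prognostic chain under clinician- and MRI-derived
baselines, and a misclassification audit listing every MS participant at or
below the cutoff with their OCB/IgG/sCD27/NFL context (sCD27 flagged against
a healthy mean + 2 SD bound). Reports are classed objects with print
methods; with `out_dir` set, a JSON report plus per-participant CSVs are
written, every reported number recomputable from the persisted tables, and
p-values pass through one formatting layer (scientific, two significant
digits) so report diffs are stable.

`supplementary` mode consumes a per-participant results table (identifier,
diagnosis, model probabilities, optionally EDSS timeline and markers)
through a declarative column mapping, rejecting unparseable diagnosis rows
with their line numbers; analyses whose columns are absent are reported
unavailable rather than guessed. `user_data` mode scores a cohort written
with `write_cohort()` using synthetically trained models.

## Problem sizes used in the tests

The packaged test-suite runs the generator at reduced scale where scale is
immaterial (72-participant cohorts, 20 noise proteins, 100–300-tree forests)
and at reference scale where the claim is about the study design itself
(160-participant validation cohorts for calibration checks over 25 seeds;
n = 300 for conversion-parameter recovery; 200 seeds for bootstrap
coverage). These sizes are stated here as the package's own choices for a
balanced, reproducible suite.

## Known limitations

* The random-forest score is statistically inefficient for weak additive
  Gaussian signal: at the staging effect size its external AUROC plateaus
  ~0.03–0.04 below the information-level ceiling. The calibration check
  encodes the ceiling and therefore documents this gap as a failing
  assertion rather than absorbing it into the generator.
* Asymptotic DeLong p-values are unreliable at very small n (see above).
* Probability calibration of real, platform-bridged historical models (which
  can sit systematically near the cutoff for controls) is not emulated;
  simulated confusion patterns at the 0.5 cutoff are therefore more
  symmetric than a miscalibrated imported model would produce.
* The packaged ratio pairings and the severity panel's protein identifiers
  are package defaults, not the historical definitions; analyses of real
  assay data must supply the true panel files.
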