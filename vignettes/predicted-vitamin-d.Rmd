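---
title: "Predicted 25(OH)D as a cohort exposure: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted 25(OH)D as a cohort exposure: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circulating 25-hydroxyvitamin D (25(OH)D) is the standard biomarker of
vitamin D status, but in a large prospective cohort it is rarely measured on
everyone, and a single blood draw reflects status only within a year or two
of collection. The *predicted 25(OH)D* approach replaces the measured
biomarker with a questionnaire-based linear score: a prediction model is
estimated on the sub-panel of cohort members with a measured value, and its
score terms are then applied to every member at every biennial questionnaire
cycle. Averaging the per-cycle scores cumulatively gives a time-updated
proxy for long-term vitamin D status, which is then related to disease
incidence (here, invasive breast cancer) through an age- and
period-stratified proportional-hazards model on exposure quartiles.

This package implements that full chain — prediction-model derivation,
exposure construction, and survival analysis — together with a calibrated
synthetic-cohort generator, so every stage can be exercised and tested
without access to any restricted cohort data.

## The prediction model

The model is ordinary least squares for measured 25(OH)D (ng/mL) on
questionnaire covariates, with three *forced adjusters* — season of blood
draw, assay laboratory, and age at draw — that control variability during
estimation but are not part of the cohort score. Candidate predictors
(supplement use, multivitamin use, dietary vitamin D, BMI, exercise,
smoking, alcohol, hormone and oral-contraceptive use, menopausal status,
ambient UV-B flux) are screened by bidirectional stepwise selection under
the Gaussian AIC

$$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2(k + 1),$$

where $k$ counts regression coefficients and the $+1$ counts the error
variance. Only AIC differences matter, so the dropped $2\pi$ constant is
irrelevant; the convention is fixed once and used for every comparison.
Three design choices here were genuinely open and are fixed as follows:

* **Direction and start.** The search is bidirectional from the
  forced-only model. Equal-AIC ties break toward the smaller model (drops
  are considered before additions).
* **Block moves.** Categorical variables enter and leave as whole blocks,
  matching how such models are conventionally reported (a hormone-use or
  BMI category never appears without its siblings).
* **Forced adjusters** are never eligible for removal.

Model performance is summarised by repeated k-fold cross-validation
(default 100 repetitions of 5-fold): per held-out fold, stepwise selection
and fitting are redone on the training four-fifths, and the Pearson
correlation between observed and predicted values plus a quartile
cross-classification are recorded. Two conventions worth noting:

* Held-out predictions use the **full linear predictor** — adjusters at
  their observed values — because the correlation is a diagnostic of model
  fit; a score-only correlation is also recorded (`r_score`) since the
  cohort score zeroes the adjusters. The full-predictor figure is the
  headline metric.
* The reported spread (`sd_r`) is the standard deviation of the 100
  repetition-level mean correlations, not of the 500 fold-level values.

Squared semi-partial correlations decompose the explained variance:
for each term, the drop in $R^2$ when that term alone is removed and the
model refitted, in percent. They are computed for score terms and
adjusters alike and reported in the conventional two-section table.

## The exposure engine

The cohort score is the intercept plus the score betas times each
indicator/continuous covariate — adjusters contribute zero by construction,
so a fully reference-level profile scores exactly the intercept
(11.94 ng/mL with the default published coefficient set). Missing
post-baseline items are last-observation-carried-forward; subjects with
missing *baseline* score predictors are excluded outright rather than
imputed, which is why the generator never masks baseline items. The
exposure at cycle $t$ is the cumulative average of scores from cycles
$0..t$; a simple per-cycle update is available as the sensitivity
exposure.

Quartile cut points default to the 25th/50th/75th percentiles of the
exposure over **all usable subject-cycles** (the person-time distribution).
The source distribution is genuinely unstated in the methodology this
package implements; the person-time choice is adopted because it makes
quartile person-years nearly equal in the survival analysis, which is the
observable property of the published person-years table. Baseline-only and
externally fixed cut points are available as options and recorded in the
scheme's provenance field. Percentiles use the $(n+1)p$ order-statistic
convention (`quantile` type 6) with linear interpolation, and a value
exactly at a cut point goes to the lower quartile.

The score from the cycle-$t$ questionnaire applies to the follow-up
interval $(t, t+2]$ years, so exposure always precedes outcome.

## The survival model

The analysis table is a counting-process expansion: one row per subject
per 2-year interval at risk, truncated at event, loss to follow-up, or
administrative end. The partial likelihood is stratified on attained age
in single years crossed with questionnaire cycle, so each age-period cell
has its own baseline hazard; estimation delegates to `survival::coxph`
with **Efron** tie handling (the tie method is a fixed convention here; a
flag exposes the alternatives). The highest quartile is the reference.
Tests and summaries:

* **Trend**: Wald test of a single ordinal exposure term (scores 1–4 by
  default; quartile-median scoring by argument). The test construction is
  a convention, not an inherited fact.
* **Subtypes**: ER+ and ER− fits censor events of the other or unknown
  subtype at diagnosis, so no event is counted twice; unknown-subtype
  events count only in the overall analysis.
* **Subgroups**: attained age (< 45 / ≥ 45, person-time split at the 45th
  birthday so one subject can appear in both), current supplement use
  (time-varying), and baseline BMI (three groups, additionally adjusted
  for continuous BMI).
* **Interaction**: likelihood-ratio test on exposure × modifier product
  terms (Wald available through the underlying fit).

Because age is stratified in single years and simulated ages are integer,
a continuous age adjustment term would be collinear within strata and is
therefore not in the default multivariable covariate set; the strata carry
the age adjustment.

## What the synthetic cohort emulates — and what it does not

The generator draws a cohort of women aged 21–69 at baseline, followed
over 10 biennial questionnaire cycles (18 years), with:

* **Covariate dynamics**: sticky first-order chains — each item keeps its
  value with probability 0.95 per cycle, otherwise it is redrawn from the
  baseline distribution, so marginals are stationary. Supplement use is
  positively associated with multivitamin use (conditional prevalences
  0.30 / 0.086, marginal 0.15). Prevalence defaults are round, plausible
  values for such a cohort (e.g. multivitamin 0.30, smoking 0.15, ~50%
  overweight or obese); none are published quantities, and all are
  overridable.
* **A biospecimen panel** drawn at the final cycle, with season,
  laboratory and age at draw attached, and measured 25(OH)D generated as
  the published linear predictor plus calibrated residual noise.
* **Outcomes** from a piecewise-constant hazard per 2-year interval:
  baseline rate 0.0016/person-year times `exp` of the quartile effect
  (true IRRs 1.25/1.10/1.05/1 for quartiles 1..4) and a BMI effect
  (0/−0.15/−0.25/−0.40 log-HR across BMI categories). The BMI effect is
  deliberately *protective* while high BMI also lowers the score — this
  reproduces the confounding structure in which adjusting for BMI moves
  the lowest-quartile IRR away from the null. Tumour receptor status is
  drawn as ER+/PR+ 50%, ER+/PR− 14%, ER−/PR+ 2%, ER−/PR− 34%, then masked
  to unknown for 15% of cases.
* **Missingness and attrition**: independent item missingness at 5% per
  post-baseline cycle and loss to follow-up at 1.5% per cycle
  (approximately 85–90% of potential person-time retained, as in large
  mailed-questionnaire cohorts). Dietary vitamin D is a standardized
  continuous intake variable (gamma-distributed, mean ≈ 10, SD ≈ 8 units)
  whose published beta applies per unit.

The generator does **not** model geography or UV-B dynamics beyond a
static high/low category, questionnaire nonresponse beyond independent
item missingness, correlated predictor trajectories (weight gain with
age, quitting smoking), or dependent censoring. Passing tests therefore
demonstrate that the *methods* behave correctly under the assumed
statistical structure — unbiased effect recovery, correct confounding
direction, nominal test levels — not that the generator reproduces every
feature of real questionnaire data.

## Noise calibration

Two published facts anchor the measured-25(OH)D distribution: the linear
predictor explains 25.2% of its variance, and its quartile cut points are
21/31/40 ng/mL. The calibration (`calibrate_panel_noise`) honours both:

1. The residual SD is fixed analytically by the variance constraint,
   $\sigma = \mathrm{sd}(\mathrm{LP})\sqrt{(1-R^2)/R^2}$.
2. The remaining freedom — a location offset $\delta$ (absorbing the
   difference between the simulated covariate mix and the population the
   printed cut points describe) and a mild skew $\lambda$ in the
   standardized residual $(e^{\lambda Z} - m_1)/s_1$ — is fitted to the
   three cut points by Nelder–Mead in quadratic loss. The skew transform
   is variance-preserving, so step 2 cannot undo step 1.

Calibrating on the same residual draws used for output makes the
empirical cut points match the targets almost exactly. Measured values
are floored at 1 ng/mL (an assay reporting floor); the fraction affected
is ~1% and is part of the generated distribution. The distributional
family of the real measurements is unknown — only quartiles and tail
fractions are printed — so the generator matches those moments rather
than a stated density; with the default covariate mix the implied
fractions below 20 and 30 ng/mL come out at ≈ 22% and ≈ 47–48%,
consistent with the published deficiency and insufficiency proportions.

## Numerical conventions and degenerate inputs

* Percentile type 6 everywhere quartiles are derived; ties at a cut point
  go down. Quartile derivation refuses distributions with fewer than 4
  distinct values or tied cut points (reported as heavy ties).
* `aic_gaussian` returns $-\infty$ for a perfect fit, so exact
  interpolation dominates any stepwise comparison; stepwise accepts a move
  only if it lowers AIC by more than $10^{-8}$.
* Rank-deficient designs are rejected with the collinear columns named; a
  candidate block that is collinear given the current model is treated as
  an unavailable move rather than an error.
* Cross-validation folds with fewer than 2 distinct training responses
  are an error; held-out folds smaller than 4 skip the quartile agreement
  (leave-one-out remains usable for prediction checks).
* Events or censorings at exactly an interval start are given a
  vanishingly small positive risk time rather than dropped.
* Strata without events contribute nothing to the partial likelihood and
  are silently dropped by the fitter, as is standard.

## Problem sizes used in the shipped checks

The package's own test battery runs the study-scale configurations it
reports on: a 2856-specimen panel with 100 repetitions of 5-fold
cross-validation for the prediction-performance figures; 100,000
simulated specimens for the distribution calibration; twenty independent
end-to-end cohorts of 20,000 subjects over 10 cycles for effect-recovery
and confounding-direction checks; and 500 null outcome replicates at
n = 1200 for the type-I error of the trend and interaction tests. These
sizes were chosen so each check's Monte Carlo error is small relative to
the tolerance it asserts.

## Known limitations

* The coefficient set treats the published betas as exact; no uncertainty
  from coefficient estimation is propagated into cohort scores.
* Imputation is last-observation-carried-forward only, mirroring the
  method it implements; no multiple imputation.
* No competing-risks modelling and no proportional-hazards diagnostics
  beyond convergence reporting.
* The linear score is additive by construction; interactions among
  questionnaire predictors are neither simulated nor selectable.
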