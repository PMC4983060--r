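# vitdpredict

Predicted 25-hydroxyvitamin D (25(OH)D) exposure modelling for prospective
cohort studies.

## What problem this solves

Measuring circulating 25(OH)D — the standard biomarker of vitamin D status —
on every member of a large cohort is rarely feasible, and a single blood
draw only reflects status within a year or two. The *predicted 25(OH)D*
approach estimates a linear prediction model on a biospecimen sub-panel and
applies its questionnaire-based score terms to the whole cohort at every
biennial questionnaire cycle. For subject $i$ at cycle $t$ the exposure is
the cumulative average of scores

$$\bar{S}_{it} = \frac{1}{t+1}\sum_{u=0}^{t} \Big(\beta_0 + \mathbf{x}_{iu}^\top \boldsymbol\beta_{\text{score}}\Big),$$

a time-updated proxy for long-term status. Disease incidence is then
modelled across exposure quartiles $q$ with a proportional-hazards model
stratified on attained age (single years) $\times$ questionnaire period,

$$\lambda(t \mid q, \mathbf{z}) = \lambda_{0,\,\text{age} \times \text{period}}(t)\, \exp\!\big(\gamma_q + \mathbf{z}^\top\boldsymbol\theta\big),$$

giving incidence rate ratios (IRRs) for each quartile relative to the
highest, a Wald trend test on an ordinal exposure term, and
subtype/subgroup/interaction analyses on counting-process person-period
data (Efron tie handling).

The package is aimed at epidemiologists and biostatisticians who want to
derive such a score (repeated 5-fold cross-validation with per-fold
stepwise-AIC selection), apply it as a time-updated exposure
(carry-forward, cumulative average, quartile assignment), and analyse it —
plus a calibrated synthetic-cohort generator so the entire pipeline runs
and is testable without restricted data.

## Worked example

```r
library(vitdpredict)

cfg <- sim_config(n_subjects = 59000, seed = 1)      # cohort conditions
cohort <- apply_missingness(generate_covariate_histories(cfg), cfg)

# biospecimen panel: published betas + noise calibrated to R^2 = 0.252 and
# quartile cut points 21/31/40 ng/mL
panel <- sample_biospecimen_panel(cohort, n_panel = 2856, config = cfg)
round(quantile(panel$measured_25ohd, c(.25, .5, .75), type = 6), 1)
#>  25%  50%  75%
#> 21.4 30.3 40.3

cv <- repeated_cv(panel, k = 5, reps = 20, seed = 1)  # reps = 100 for the full run
cv
#> <cv_performance> 20 x 5-fold cross-validation, n = 2856
#>   mean test-fold r     0.496 (SD of repetition means 0.003)
#>   mean test-fold R^2   0.247
#>   same quartile        39.1%
#>   same or adjacent     80.6%

expo <- score_cohort(cohort)                  # carry-forward, cumulative average, quartiles
outcomes <- simulate_outcomes(carry_forward(cohort), expo, cfg)
pp <- expand_person_periods(carry_forward(cohort), outcomes, expo)

fit_cox(pp)                                   # multivariable-adjusted, age/period-stratified
#> <vitd_cox> outcome all, quartile coding, 1471 events / 494806 records
#> # A tibble: 4 × 6
#>   quartile events person_years   irr conf_low conf_high
#>      <int>  <int>        <dbl> <dbl>    <dbl>     <dbl>
#> 1        4    371      245698. 1       NA         NA
#> 2        3    357      242358. 0.983    0.850      1.14
#> 3        2    355      243845. 0.995    0.859      1.15
#> 4        1    388      248885. 1.14     0.975      1.32
```

Reading the output: the panel's empirical quartile cut points land on the
calibration targets; cross-validated correlation ≈ 0.50 means the score
explains about a quarter of biomarker variance out of sample — enough to
*rank* subjects (39% land in the same quartile, 81% within one) though not
to predict individuals. In this simulated cohort the true lowest-quartile
IRR is 1.25; this draw estimates 1.14 (95% CI 0.98–1.32), within sampling
error at ~1500 events. The age/period-only estimate for the same contrast
is 1.03 — attenuated toward the null, because high BMI lowers the score
while (in these data) also lowering incidence, so BMI adjustment moves the
estimate away from 1. `trend_test(pp)`, `subtype_analysis(pp, "ER+")`,
`subgroup_analysis(pp, "bmi_baseline")` and `interaction_test(pp,
"bmi_cat")` give the companion analyses; `tidy()`/`glance()` and
`autoplot()` work on the fitted objects.

`run_pipeline(default_run_config())` executes
simulate → derive → score → analyze end to end, writing all tables as
commented CSV plus a plain-text report; `inst/scripts/run_pipeline.R` is a
thin command-line wrapper.

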