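# Minimal hand-built cohort/outcome/exposure tables for expansion tests.
toy_cohort <- function(n_cycles = 10) {
  tibble::tibble(subject_id = 1L, cycle = 0:(n_cycles - 1),
                 age = 50L + 2L * (0:(n_cycles - 1)), age_baseline = 50L)
}
toy_exposure <- function(n_cycles = 10, q = 2L) {
  tibble::tibble(subject_id = 1L, cycle = 0:(n_cycles - 1),
                 exposure = 15, quartile = q)
}

test_that("person-period expansion follows the truncation and accounting rules", {
  # full follow-up, no event: 9 biennial risk rows, 18 person-years
  oc <- tibble::tibble(subject_id = 1L, event = 0L, event_cycle = NA_integer_,
                       event_time = NA_real_, subtype = NA_character_,
                       censor_cycle = 8L, censor_time = 2, futime = 18)
  pp <- expand_person_periods(toy_cohort(), oc, toy_exposure())
  expect_equal(nrow(pp), 9)
  expect_equal(sum(pp$time), 18)
  expect_equal(pp$age_year, seq(50, 66, by = 2))

  # event 1.0 y into cycle 3: rows 0..3 only, last row truncated with event
  oc2 <- tibble::tibble(subject_id = 1L, event = 1L, event_cycle = 3L,
                        event_time = 1.0, subtype = "ER+",
                        censor_cycle = 3L, censor_time = 1.0, futime = 7)
  pp2 <- expand_person_periods(toy_cohort(), oc2, toy_exposure())
  expect_equal(pp2$cycle, 0:3)
  expect_equal(pp2$time, c(2, 2, 2, 1))
  expect_equal(pp2$event, c(0L, 0L, 0L, 1L))
  expect_equal(pp2$event_erpos, c(0L, 0L, 0L, 1L))

  expect_error(expand_person_periods(toy_cohort(),
                                     dplyr::mutate(oc, subject_id = 99L),
                                     toy_exposure()),
               "absent")
})

test_that("stratified Efron fit matches brute-force partial-likelihood maximization", {
  # single stratum, 6 subjects, one tied event pair
  toy <- tibble::tibble(
    time = c(1.0, 1.0, 1.5, 2.0, 2.0, 2.0),
    .event = c(1L, 1L, 0L, 1L, 0L, 0L),
    stratum = 1L,
    x = c(1, 0, 1, 0, 1, 0))
  cox <- survival::coxph(survival::Surv(time, .event) ~ x, data = toy,
                         ties = "efron")
  oracle <- efron_mle(toy$time, toy$.event, toy$stratum, toy$x)
  expect_equal(unname(coef(cox)), oracle, tolerance = 1e-6)

  # two strata, 10 subjects, ties in each stratum
  set.seed(14)
  toy2 <- tibble::tibble(
    time = c(1, 1, 2, 2, 3, 1, 1, 1, 2, 3),
    .event = c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L),
    stratum = rep(1:2, each = 5),
    x = rnorm(10))
  cox2 <- survival::coxph(survival::Surv(time, .event) ~ x + strata(stratum),
                          data = toy2, ties = "efron")
  oracle2 <- efron_mle(toy2$time, toy2$.event, toy2$stratum, toy2$x)
  expect_equal(unname(coef(cox2)), oracle2, tolerance = 1e-6)

  # and the package wrapper agrees with the oracle through its own interface
  pp <- tibble::tibble(
    subject_id = 1:8, cycle = 0L, age_year = 50L,
    time = c(1, 1, 1.5, 2, 2, 2, 1.2, 0.7),
    event = c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L),
    event_erpos = 0L, event_erneg = 0L, subtype = NA_character_,
    quartile = c(1L, 4L, 1L, 4L, 1L, 4L, 1L, 4L), exposure = 10)
  fit <- fit_cox(pp, covariates = NULL)
  xind <- as.integer(pp$quartile == 1)  # single contrast: Q1 vs Q4
  oracle3 <- efron_mle(pp$time, pp$event, pp$age_year, xind)
  expect_equal(fit$terms$log_hr[fit$terms$term == ".qfac1"], oracle3,
               tolerance = 1e-6)
})

test_that("collapsing homogeneous strata leaves the estimate unchanged", {
  pp <- make_test_pp(n_subjects = 1500, seed = 61, baseline_hazard = 0.01)
  one <- dplyr::mutate(pp, age_year = 1L, cycle = 0L)
  fit_wrap <- fit_cox(one, covariates = NULL)
  plain <- survival::coxph(
    survival::Surv(time, event) ~ factor(quartile, levels = c(4, 3, 2, 1)),
    data = one, ties = "efron")
  expect_equal(unname(fit_wrap$terms$log_hr), unname(coef(plain)),
               tolerance = 1e-6)
})

test_that("null simulations give IRRs near 1 and true effects are recovered", {
  cfg <- sim_config(n_subjects = 20000, n_cycles = 6, seed = 101,
                    baseline_hazard = 0.004,
                    quartile_log_hr = rep(0, 4), bmi_log_hr = rep(0, 4))
  co <- generate_covariate_histories(cfg)
  expo <- score_cohort(co)
  oc <- simulate_outcomes(co, expo, cfg)
  pp <- expand_person_periods(co, oc, expo)
  fit <- fit_cox(pp, covariates = NULL)
  expect_true(all(abs(fit$terms$log_hr[startsWith(fit$terms$term, ".qfac")])
                  < 3 * fit$terms$se[startsWith(fit$terms$term, ".qfac")]))

  cfg2 <- sim_config(n_subjects = 20000, n_cycles = 6, seed = 102,
                     baseline_hazard = 0.004)
  oc2 <- simulate_outcomes(co, expo, cfg2)
  pp2 <- expand_person_periods(co, oc2, expo)
  fit2 <- fit_cox(pp2)
  q1 <- fit2$terms[fit2$terms$term == ".qfac1", ]
  expect_lt(abs(q1$log_hr - log(1.25)), 3 * q1$se)
})

test_that("trend test is invariant to reversing the ordinal coding", {
  pp <- make_test_pp(n_subjects = 3000, seed = 77, baseline_hazard = 0.01)
  a <- trend_test(pp, covariates = NULL, trend_scores = 1:4)
  b <- trend_test(pp, covariates = NULL, trend_scores = 4:1)
  expect_equal(a$log_hr, -b$log_hr, tolerance = 1e-8)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
})

test_that("subtype analyses censor other subtypes and conserve events", {
  pp <- make_test_pp(n_subjects = 5000, seed = 85, baseline_hazard = 0.01)
  total <- sum(pp$event)
  erp <- sum(pp$event_erpos); ern <- sum(pp$event_erneg)
  unk <- sum(pp$event == 1L & pp$subtype == "unknown", na.rm = TRUE)
  expect_equal(erp + ern + unk, total)

  fit_p <- subtype_analysis(pp, "ER+", covariates = NULL)
  expect_equal(fit_p$n_event, erp)

  # relabelling every event ER+ makes the subtype fit equal the overall fit
  pp_all <- dplyr::mutate(pp,
    subtype = ifelse(event == 1L, "ER+", NA_character_),
    event_erpos = event, event_erneg = 0L)
  fit_sub <- subtype_analysis(pp_all, "ER+", covariates = NULL)
  fit_all <- fit_cox(pp_all, covariates = NULL)
  expect_equal(fit_sub$terms$log_hr, fit_all$terms$log_hr, tolerance = 1e-10)
})

test_that("subgroup analyses conserve person-time and respect stratifiers", {
  pp <- make_test_pp(n_subjects = 5000, seed = 93, baseline_hazard = 0.01)
  sg <- subgroup_analysis(pp, "age45", covariates = NULL)
  expect_equal(sum(sg$person_years), sum(pp$time), tolerance = 1e-8)
  expect_equal(sum(sg$n_event), sum(pp$event))

  # a constant stratifier reduces to the unstratified fit
  pp$onegrp <- "all"
  sg1 <- subgroup_analysis(pp, "onegrp", covariates = NULL)
  expect_equal(nrow(sg1), 1)
  expect_equal(sg1$result[[1]]$terms$log_hr,
               fit_cox(pp, covariates = NULL)$terms$log_hr, tolerance = 1e-10)

  sgb <- subgroup_analysis(pp, "bmi_baseline", covariates = c("bmi"))
  expect_setequal(sgb$stratum, c("<25", "25-<30", ">=30"))
})

test_that("interaction test is a definitional likelihood-ratio comparison", {
  pp <- make_test_pp(n_subjects = 4000, seed = 55, baseline_hazard = 0.01)
  it <- interaction_test(pp, "family_history", covariates = NULL)
  expect_equal(it$df, 1)
  ll1 <- it$fit_interaction$loglik[2]; ll0 <- it$fit_null$loglik[2]
  expect_equal(it$statistic, 2 * (ll1 - ll0))
  expect_equal(it$p_value, pchisq(2 * (ll1 - ll0), 1, lower.tail = FALSE))
  expect_gte(it$p_value, 0)
})
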