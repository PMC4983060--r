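test_that("covariate histories have one row per subject-cycle and are seed-reproducible", {
  cfg <- sim_config(n_subjects = 100, n_cycles = 10, seed = 42)
  co <- generate_covariate_histories(cfg)
  expect_equal(nrow(co), 100 * 10)
  expect_equal(dplyr::count(co, subject_id)$n, rep(10, 100))
  co2 <- generate_covariate_histories(cfg)
  expect_identical(co, co2)
  # a different seed must actually change the draw
  co3 <- generate_covariate_histories(cfg, seed = 43)
  expect_false(identical(co$supplement, co3$supplement))
})

test_that("baseline prevalences match the configured values within Monte Carlo error", {
  n <- 50000
  cfg <- sim_config(n_subjects = n, n_cycles = 2, seed = 7)
  base <- dplyr::filter(generate_covariate_histories(cfg), cycle == 0)
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(mean(base$supplement) - 0.15), 3 * se)
  se_mv <- sqrt(0.30 * 0.70 / n)
  expect_lt(abs(mean(base$multivitamin) - 0.30), 3 * se_mv)
  # sticky chains keep marginals stationary across cycles
  later <- dplyr::filter(generate_covariate_histories(cfg), cycle == 1)
  expect_lt(abs(mean(later$supplement) - 0.15), 4 * se)
})

test_that("configuration errors are rejected by name", {
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(quartile_targets = c(31, 21, 40)), "quartile_targets")
  expect_error(sim_config(er_distribution = c(0.5, 0.5, 0.1, 0.1)),
               "er_distribution")
  expect_error(sim_config(n_cycles = 1), "n_cycles")
  expect_error(sim_config(quartile_log_hr = log(c(1.2, 1.1, 1.0, 0.9))),
               "reference")
})

test_that("noise-free panel equals its linear predictor; calibration hits R2 and cut points", {
  cfg <- sim_config(n_subjects = 6000, n_cycles = 2, seed = 13)
  co <- generate_covariate_histories(cfg)
  p0 <- sample_biospecimen_panel(co, n_panel = 500, config = cfg,
                                 residual_sd = 0)
  expect_equal(p0$measured_25ohd, p0$lp, tolerance = 1e-12)

  p <- sample_biospecimen_panel(co, n_panel = 2856, config = cfg)
  cal <- attr(p, "calibration")
  expect_equal(cal$achieved_r2, 0.252, tolerance = 1e-6)
  cuts <- quantile(p$measured_25ohd, c(0.25, 0.5, 0.75), type = 6)
  expect_equal(unname(cuts), c(21, 31, 40), tolerance = 0.02)
  expect_error(sample_biospecimen_panel(co, n_panel = 10^6, config = cfg),
               "exceeds")
})

test_that("missingness masks post-baseline items at the configured rate, never baseline", {
  cfg <- sim_config(n_subjects = 2000, n_cycles = 6, seed = 3,
                    missing_rate = 0.1)
  co <- generate_covariate_histories(cfg)
  expect_identical(apply_missingness(co, sim_config(n_subjects = 2000,
                                                    n_cycles = 6,
                                                    missing_rate = 0)), co)
  m1 <- apply_missingness(co, sim_config(n_subjects = 2000, n_cycles = 6,
                                         missing_rate = 1, seed = 3))
  base <- dplyr::filter(m1, cycle == 0)
  post <- dplyr::filter(m1, cycle > 0)
  expect_false(anyNA(base[, maskable_columns()]))
  expect_true(all(is.na(post$supplement)))
  expect_true(all(is.na(post$bmi)))

  m <- apply_missingness(co, cfg)
  post_items <- as.matrix(is.na(dplyr::filter(m, cycle > 0)[,
    c("supplement", "multivitamin", "dietary_vitd", "hormone_use",
      "vigorous_activity", "walking", "alcohol", "smoking",
      "oc_recent", "oc_ge10y")]))
  n_items <- length(post_items)
  se <- sqrt(0.1 * 0.9 / n_items)
  expect_lt(abs(mean(post_items) - 0.1), 3 * se)
})

test_that("event counts scale with the hazard and subtype draws match their distribution", {
  cfg1 <- sim_config(n_subjects = 20000, n_cycles = 6, seed = 21,
                     baseline_hazard = 0.002,
                     quartile_log_hr = c(0, 0, 0, 0), bmi_log_hr = rep(0, 4),
                     ltfu_rate = 0)
  co <- generate_covariate_histories(cfg1)
  expo <- score_cohort(co, vitd_coefficients())
  oc1 <- simulate_outcomes(co, expo, cfg1)
  cfg2 <- sim_config(n_subjects = 20000, n_cycles = 6, seed = 21,
                     baseline_hazard = 0.004,
                     quartile_log_hr = c(0, 0, 0, 0), bmi_log_hr = rep(0, 4),
                     ltfu_rate = 0)
  oc2 <- simulate_outcomes(co, expo, cfg2)
  # small-hazard regime: expected events ~ n * person-time * hazard, so the
  # ratio of counts approximates the hazard ratio 2; binomial error bounds
  n1 <- sum(oc1$event); n2 <- sum(oc2$event)
  expect_gt(n1, 100)
  expect_lt(abs(n2 / n1 - 2), 2 * sqrt(1 / n1 + 1 / n2) * 2)

  known <- oc1$receptor_joint[!is.na(oc1$receptor_joint)]
  freq <- prop.table(table(factor(known, c("ER+/PR+", "ER+/PR-",
                                           "ER-/PR+", "ER-/PR-"))))
  target <- c(0.50, 0.14, 0.02, 0.34)
  se <- sqrt(target * (1 - target) / length(known))
  expect_true(all(abs(freq - target) < 3 * pmax(se, 1e-3)))
})

test_that("no subject accrues person-time after event or censoring", {
  cfg <- sim_config(n_subjects = 2000, n_cycles = 8, seed = 9,
                    baseline_hazard = 0.01, ltfu_rate = 0.05)
  co <- generate_covariate_histories(cfg)
  expo <- score_cohort(co, vitd_coefficients())
  oc <- simulate_outcomes(co, expo, cfg)
  pp <- expand_person_periods(co, oc, expo)
  last_cycle <- dplyr::summarise(dplyr::group_by(pp, subject_id),
                                 mx = max(cycle), n = dplyr::n())
  stop_cycle <- oc$censor_cycle[match(last_cycle$subject_id, oc$subject_id)]
  expect_equal(last_cycle$mx, stop_cycle)
  expect_equal(last_cycle$n, stop_cycle + 1L)
  # person-time additivity against a per-subject oracle
  expect_equal(sum(pp$time), sum(oc$futime), tolerance = 1e-8)
})
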