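test_that("reference profile scores the intercept and printed betas add linearly", {
  expect_equal(compute_score(reference_profile()), 11.94)
  expect_equal(compute_score(reference_profile(supplement = 1L)),
               11.94 + 9.66)
  expect_equal(compute_score(reference_profile(
    bmi_cat = factor(">=35", levels = bmi_levels()),
    alcohol = factor("ge7_wk", levels = c("none", "1-6_wk", "ge7_wk")),
    smoking = 1L)),
    11.94 - 4.71 - 2.97 - 1.58)
})

test_that("the score is linear in disjoint non-reference terms", {
  a <- reference_profile(supplement = 1L, multivitamin = 1L)
  b <- reference_profile(smoking = 1L,
                         hormone_use = factor("current_lt5",
                                              levels = levels(reference_profile()$hormone_use)))
  ab <- reference_profile(supplement = 1L, multivitamin = 1L, smoking = 1L,
                          hormone_use = b$hormone_use)
  expect_equal(compute_score(a) + compute_score(b) -
                 compute_score(reference_profile()),
               compute_score(ab))
})

test_that("adjustment terms never enter the cohort score", {
  prof <- reference_profile()
  prof$season <- factor("winter", levels = c("summer", "winter", "other"))
  prof$age_at_draw <- 60
  prof$uvb_high <- 1L
  expect_equal(compute_score(prof), 11.94)
})

test_that("carry-forward fills gaps from the most recent observation", {
  hist <- tibble::tibble(
    subject_id = 1L, cycle = 0:4,
    supplement = c(1L, 0L, NA, NA, 1L),
    dietary_vitd = c(5, NA, NA, NA, NA),
    alcohol = factor(c("none", "1-6_wk", NA, "ge7_wk", NA),
                     levels = c("none", "1-6_wk", "ge7_wk")))
  out <- carry_forward(hist, items = c("supplement", "dietary_vitd", "alcohol"))
  expect_equal(out$supplement, c(1L, 0L, 0L, 0L, 1L))
  expect_equal(out$dietary_vitd, rep(5, 5))   # all post-baseline take baseline
  expect_equal(as.character(out$alcohol),
               c("none", "1-6_wk", "1-6_wk", "ge7_wk", "ge7_wk"))
  expect_equal(out$carried_any, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  # complete input passes through unchanged
  full <- tibble::tibble(subject_id = rep(1:2, each = 2), cycle = rep(0:1, 2),
                         supplement = c(1L, 1L, 0L, 0L))
  expect_equal(carry_forward(full, items = "supplement")$supplement,
               full$supplement)
  # missing baseline is a hard error, not silent imputation
  bad <- tibble::tibble(subject_id = 1L, cycle = 0:1,
                        supplement = c(NA, 1L))
  expect_error(carry_forward(bad, items = "supplement"), "baseline")
})

test_that("cumulative average is the prefix mean and contracts toward history", {
  expect_equal(cumulative_average(c(7, 7, 7)), c(7, 7, 7))
  expect_equal(cumulative_average(c(10, 20, 30)), c(10, 15, 20))
  set.seed(99)
  x <- rnorm(9, 20, 5)
  oracle <- vapply(seq_along(x), function(t) mean(x[1:t]), numeric(1))
  expect_equal(cumulative_average(x), oracle)
  expect_error(cumulative_average(numeric(0)), "non-empty")
  # contraction: each update moves at most as far as the new score is
  for (rep in 1:20) {
    x <- rnorm(10, 20, 8)
    ca <- cumulative_average(x)
    expect_true(all(abs(diff(ca)) <= abs(x[-1] - ca[-length(ca)]) + 1e-12))
  }
  # simple update is the identity, and coincides on constants
  expect_identical(simple_update(c(10, 20, 30)), c(10, 20, 30))
  expect_identical(simple_update(rep(4, 5)), cumulative_average(rep(4, 5)))
})

test_that("quartile derivation uses the documented percentile convention and tie rule", {
  sch <- derive_quartiles(1:100)
  expect_equal(sch$cuts, c(25.25, 50.5, 75.75))
  expect_equal(assign_quartile(c(25.25, 25.26, 50.5, 75.75, 75.76), sch),
               c(1L, 2L, 2L, 3L, 4L))
  expect_error(derive_quartiles(rep(3, 50)), "distinct")
  expect_error(derive_quartiles(c(rep(1, 97), 2, 3, 4)), "ties")
})

test_that("cohort scoring partitions person-time into near-equal quartiles", {
  cfg <- sim_config(n_subjects = 3000, n_cycles = 8, seed = 31,
                    missing_rate = 0.08)
  co <- apply_missingness(generate_covariate_histories(cfg), cfg)
  expo <- score_cohort(co)
  expect_equal(nrow(expo), nrow(co))
  expect_true(all(expo$quartile %in% 1:4))
  shares <- prop.table(table(expo$quartile))
  expect_true(all(abs(shares - 0.25) < 0.02))
  # cumulative average matches a per-subject prefix-mean oracle
  one <- dplyr::filter(expo, subject_id == expo$subject_id[[1]])
  expect_equal(one$exposure, cumulative_average(one$score))
  # simple update reproduces the per-cycle scores as exposure
  simple <- score_cohort(co, exposure = "simple")
  expect_equal(simple$exposure, simple$score)
})
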