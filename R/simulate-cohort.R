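#' Configuration for the synthetic cohort generator
#'
#' Bundles every constant the generator needs: cohort size and number of
#' biennial questionnaire cycles, baseline predictor prevalences, per-cycle
#' covariate switch probabilities, the biomarker noise calibration targets,
#' the outcome hazard model, tumour-subtype distribution, and the missingness
#' and loss-to-follow-up rates. Defaults emulate a large cohort of adult
#' women followed by mailed questionnaires every two years for 18 years, with
#' a measured-biomarker sub-panel drawn at the final cycle.
#'
#' Prevalences are round values typical of such a cohort (they are not
#' published quantities); the biomarker calibration targets are: quartile cut
#' points of measured 25(OH)D at 21/31/40 ng/mL and a prediction-model
#' proportion of variance explained of 0.252.
#'
#' @param n_subjects Number of cohort members.
#' @param n_cycles Number of biennial questionnaire cycles (>= 2); cycles are
#'   indexed `0:(n_cycles - 1)` at two-year spacing.
#' @param predictor_prevalences Named list of baseline prevalences /
#'   category distributions; see `default_prevalences()` for the full set of
#'   names. Supplied entries override defaults item by item.
#' @param covariate_transition_probs Named numeric vector of per-cycle switch
#'   probabilities for time-varying items; a scalar recycles to all items.
#'   Chains are "sticky": with probability `1 - p` the previous value is
#'   kept, otherwise a fresh value is drawn from the baseline distribution,
#'   so marginals are stationary across cycles.
#' @param residual_sd Residual SD of measured 25(OH)D about its linear
#'   predictor, in ng/mL. `NULL` (default) requests calibration so the
#'   linear predictor explains `r2_target` of the marginal variance.
#' @param r2_target Population proportion of 25(OH)D variance explained by
#'   the full linear predictor; used when `residual_sd` is `NULL`.
#' @param quartile_targets Three strictly increasing ng/mL cut points the
#'   simulated marginal distribution of measured 25(OH)D is calibrated to.
#' @param baseline_hazard Breast-cancer hazard, events per person-year, for
#'   the reference profile (highest exposure quartile, BMI < 25).
#' @param quartile_log_hr Log hazard ratios for exposure quartiles 1..4;
#'   the fourth (highest-score) quartile is the reference and must be 0.
#' @param bmi_log_hr Log hazard ratios for the four BMI categories
#'   (< 25 reference, then 25-29.9, 30-34.9, >= 35). The default is negative
#'   in higher categories, giving BMI the confounding direction the analysis
#'   must undo: high BMI lowers the predicted score *and* lowers the hazard.
#' @param er_distribution Probabilities for joint receptor status
#'   ER+/PR+, ER+/PR-, ER-/PR+, ER-/PR- among cases; must sum to 1.
#' @param er_unknown_rate Fraction of cases whose receptor status is
#'   subsequently masked to "unknown".
#' @param missing_rate Per-item, per-cycle probability that a post-baseline
#'   questionnaire item is missing.
#' @param ltfu_rate Per-cycle probability of loss to follow-up.
#' @param seed Integer seed; every stochastic operation that consumes the
#'   config derives its randomness from this.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20000L,
                       n_cycles = 10L,
                       predictor_prevalences = list(),
                       covariate_transition_probs = 0.05,
                       residual_sd = NULL,
                       r2_target = 0.252,
                       quartile_targets = c(21, 31, 40),
                       baseline_hazard = 0.0016,
                       quartile_log_hr = log(c(1.25, 1.10, 1.05, 1.00)),
                       bmi_log_hr = c(0, -0.15, -0.25, -0.40),
                       er_distribution = c(0.50, 0.14, 0.02, 0.34),
                       er_unknown_rate = 0.15,
                       missing_rate = 0.05,
                       ltfu_rate = 0.015,
                       seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_cycles <- assert_count(n_cycles, "n_cycles", min = 2L)
  prev <- utils::modifyList(default_prevalences(), predictor_prevalences)
  prob_items <- c("multivitamin", "supplement_given_multi", "supplement_given_nomulti",
                  "bmi_cat", "hormone_use", "vigorous_activity", "walking",
                  "alcohol", "smoking", "oc_recent", "oc_ge10y", "uvb_high",
                  "family_history", "parity", "age_first_birth", "age_menarche",
                  "season", "lab")
  for (nm in prob_items) {
    assert_prob(prev[[nm]], paste0("predictor_prevalences$", nm))
  }
  tv <- time_varying_items()
  if (length(covariate_transition_probs) == 1L && is.null(names(covariate_transition_probs))) {
    covariate_transition_probs <- stats::setNames(
      rep(covariate_transition_probs, length(tv)), tv)
  } else {
    base <- stats::setNames(rep(0.05, length(tv)), tv)
    base[names(covariate_transition_probs)] <- covariate_transition_probs
    covariate_transition_probs <- base
  }
  assert_prob(covariate_transition_probs, "covariate_transition_probs")
  if (!is.null(residual_sd) && (!is.finite(residual_sd) || residual_sd < 0)) {
    stop("configuration error: `residual_sd` must be a non-negative number",
         call. = FALSE)
  }
  if (length(quartile_targets) != 3L || any(diff(quartile_targets) <= 0)) {
    stop("configuration error: `quartile_targets` must be three strictly increasing cut points",
         call. = FALSE)
  }
  if (length(quartile_log_hr) != 4L || !all(is.finite(quartile_log_hr))) {
    stop("configuration error: `quartile_log_hr` must be four finite log hazard ratios",
         call. = FALSE)
  }
  if (abs(quartile_log_hr[4]) > 1e-12) {
    stop("configuration error: quartile 4 (highest) is the reference; its log-HR must be 0",
         call. = FALSE)
  }
  if (length(er_distribution) != 4L || abs(sum(er_distribution) - 1) > 1e-8) {
    stop("configuration error: `er_distribution` must be four probabilities summing to 1",
         call. = FALSE)
  }
  assert_prob(er_distribution, "er_distribution")
  assert_prob(er_unknown_rate, "er_unknown_rate")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(ltfu_rate, "ltfu_rate")
  if (!is.finite(baseline_hazard) || baseline_hazard < 0) {
    stop("configuration error: `baseline_hazard` must be non-negative", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_cycles = n_cycles,
         predictor_prevalences = prev,
         covariate_transition_probs = covariate_transition_probs,
         residual_sd = residual_sd, r2_target = r2_target,
         quartile_targets = quartile_targets,
         baseline_hazard = baseline_hazard,
         quartile_log_hr = quartile_log_hr,
         bmi_log_hr = bmi_log_hr,
         er_distribution = er_distribution,
         er_unknown_rate = er_unknown_rate,
         missing_rate = missing_rate, ltfu_rate = ltfu_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Questionnaire items that evolve between cycles (and may go missing).
time_varying_items <- function() {
  c("supplement", "multivitamin", "dietary_vitd", "bmi_block",
    "hormone_use", "vigorous_activity", "walking", "alcohol",
    "smoking", "oc_recent", "oc_ge10y")
}

# Columns masked by apply_missingness / restored by carry_forward.
maskable_columns <- function() {
  c("supplement", "multivitamin", "dietary_vitd", "bmi", "bmi_cat",
    "hormone_use", "vigorous_activity", "walking", "alcohol",
    "smoking", "oc_recent", "oc_ge10y")
}

default_prevalences <- function() {
  list(
    multivitamin = 0.30,
    # supplement use is positively associated with multivitamin use;
    # conditional prevalences give a 0.15 marginal
    supplement_given_multi = 0.30,
    supplement_given_nomulti = 0.0857,
    dietary_shape = 1.5, dietary_scale = 6.5,  # gamma, energy-adjusted units
    bmi_cat = c("<25" = 0.28, "25-29.9" = 0.30, "30-34.9" = 0.22, ">=35" = 0.20),
    hormone_use = c(none = 0.55, past_ge5 = 0.15, current_lt5 = 0.15,
                    current_ge5 = 0.15),
    vigorous_activity = 0.30,
    walking = 0.45,
    alcohol = c(none = 0.65, "1-6_wk" = 0.25, ge7_wk = 0.10),
    smoking = 0.15,
    oc_recent = 0.10,
    oc_ge10y = 0.25,
    uvb_high = 0.40,
    family_history = 0.10,
    parity = c("0" = 0.25, "1" = 0.25, "2" = 0.30, "ge3" = 0.20),
    age_first_birth = c("<20" = 0.30, "20-24" = 0.40, ">=25" = 0.30),
    age_menarche = c("<=11" = 0.25, "12-13" = 0.50, ">=14" = 0.25),
    age_range = c(21L, 69L),
    menopause_mean = 50, menopause_sd = 3.5,
    season = c(summer = 0.30, winter = 0.30, other = 0.40),
    lab = c(1 / 3, 1 / 3, 1 / 3),
    lab_effects = c(0, 0.5, -0.5)
  )
}

bmi_levels <- function() c("<25", "25-29.9", "30-34.9", ">=35")

draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs), levels = names(probs))
}

# Draw continuous BMI within a category (uniform within conventional bands).
draw_bmi_cont <- function(cat) {
  lo <- c("<25" = 18.5, "25-29.9" = 25, "30-34.9" = 30, ">=35" = 35)[as.character(cat)]
  hi <- c("<25" = 25, "25-29.9" = 30, "30-34.9" = 35, ">=35" = 45)[as.character(cat)]
  stats::runif(length(cat), lo, hi)
}

# One fresh draw of every time-varying item for n subjects.
draw_time_varying <- function(n, prev) {
  multivitamin <- stats::rbinom(n, 1L, prev$multivitamin)
  p_supp <- ifelse(multivitamin == 1L, prev$supplement_given_multi,
                   prev$supplement_given_nomulti)
  bmi_cat <- factor(sample(bmi_levels(), n, replace = TRUE, prob = prev$bmi_cat),
                    levels = bmi_levels())
  tibble::tibble(
    supplement = stats::rbinom(n, 1L, p_supp),
    multivitamin = multivitamin,
    dietary_vitd = stats::rgamma(n, shape = prev$dietary_shape,
                                 scale = prev$dietary_scale),
    bmi_cat = bmi_cat,
    bmi = draw_bmi_cont(bmi_cat),
    hormone_use = draw_cat(n, prev$hormone_use),
    vigorous_activity = stats::rbinom(n, 1L, prev$vigorous_activity),
    walking = stats::rbinom(n, 1L, prev$walking),
    alcohol = draw_cat(n, prev$alcohol),
    smoking = stats::rbinom(n, 1L, prev$smoking),
    oc_recent = stats::rbinom(n, 1L, prev$oc_recent),
    oc_ge10y = stats::rbinom(n, 1L, prev$oc_ge10y)
  )
}

#' Generate biennial covariate histories for a synthetic cohort
#'
#' Draws one subject history per cohort member: baseline values of every
#' questionnaire item from the configured prevalences, then per-cycle
#' evolution as sticky first-order chains (with the configured switch
#' probability an item is redrawn from its baseline distribution, otherwise
#' it is kept). Static attributes — baseline age, ambient UV-B category,
#' family history, parity, ages at first birth/menarche, age at menopause —
#' are drawn once. Menopausal status is deterministic given attained age and
#' age at menopause, and the hormone-use item is forced to "none" while
#' premenopausal.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with `n_subjects * n_cycles` rows, one per subject-cycle,
#'   sorted by `subject_id` then `cycle` (0-based), with attained `age` and
#'   all covariates described above.
#' @export
generate_covariate_histories <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else seed
  prev <- config$predictor_prevalences
  n <- config$n_subjects
  with_seed(spawn_seed(seed, 101L), {
    age_baseline <- sample(seq(prev$age_range[1], prev$age_range[2]), n, replace = TRUE)
    statics <- tibble::tibble(
      subject_id = seq_len(n),
      age_baseline = as.integer(age_baseline),
      uvb_high = stats::rbinom(n, 1L, prev$uvb_high),
      family_history = stats::rbinom(n, 1L, prev$family_history),
      parity = draw_cat(n, prev$parity),
      age_first_birth = draw_cat(n, prev$age_first_birth),
      age_menarche = draw_cat(n, prev$age_menarche),
      age_menopause = round(stats::rnorm(n, prev$menopause_mean, prev$menopause_sd))
    )
    switch_p <- config$covariate_transition_probs
    cur <- draw_time_varying(n, prev)
    cycles <- vector("list", config$n_cycles)
    for (t in seq_len(config$n_cycles) - 1L) {
      if (t > 0L) {
        fresh <- draw_time_varying(n, prev)
        for (item in time_varying_items()) {
          cols <- if (item == "bmi_block") c("bmi_cat", "bmi") else item
          flip <- stats::runif(n) < switch_p[[item]]
          for (cl in cols) cur[[cl]][flip] <- fresh[[cl]][flip]
        }
      }
      cyc <- cur
      cyc$subject_id <- seq_len(n)
      cyc$cycle <- t
      cycles[[t + 1L]] <- cyc
    }
    cohort <- dplyr::bind_rows(cycles)
    cohort <- dplyr::left_join(cohort, statics, by = "subject_id")
    cohort$age <- cohort$age_baseline + 2L * cohort$cycle
    cohort$menopausal <- factor(ifelse(cohort$age >= cohort$age_menopause, "post", "pre"),
                                levels = c("pre", "post"))
    # hormone therapy is only defined after menopause
    cohort$hormone_use[cohort$menopausal == "pre"] <- "none"
    cohort$age_menopause_cat <- factor(
      ifelse(cohort$menopausal == "pre", "premenopausal",
             ifelse(cohort$age_menopause < 45, "<45",
                    ifelse(cohort$age_menopause < 50, "45-49", ">=50"))),
      levels = c("premenopausal", "<45", "45-49", ">=50"))
    cohort$hormone_ep_ge5 <- as.integer(cohort$hormone_use == "current_ge5")
    dplyr::arrange(
      dplyr::select(cohort, "subject_id", "cycle", "age", dplyr::everything()),
      .data$subject_id, .data$cycle)
  })
}

#' Mask post-baseline questionnaire items at random
#'
#' Applies independent item-level missingness to the time-varying
#' questionnaire items at every post-baseline cycle, at the configured
#' `missing_rate`. Baseline (cycle 0) score predictors are never masked:
#' subjects with incomplete baseline data are excluded from the analysis
#' rather than imputed, so the generator keeps baseline complete by
#' construction. BMI category and continuous BMI are masked jointly (they
#' come from the same questionnaire item).
#'
#' @param cohort A covariate-history table from
#'   [generate_covariate_histories()].
#' @param config A [sim_config()]; only `missing_rate` and `seed` are used.
#' @param seed Optional seed overriding `config$seed`.
#' @return The cohort table with `NA`s injected post-baseline.
#' @export
apply_missingness <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_prob(config$missing_rate, "missing_rate")
  if (config$missing_rate == 0) return(cohort)
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(spawn_seed(seed, 202L), {
    post <- cohort$cycle > 0L
    items <- time_varying_items()
    for (item in items) {
      cols <- if (item == "bmi_block") c("bmi_cat", "bmi") else item
      mask <- post & (stats::runif(nrow(cohort)) < config$missing_rate)
      for (cl in cols) cohort[[cl]][mask] <- NA
    }
    cohort
  })
}
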