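#' Expand a cohort into counting-process person-period records
#'
#' Builds the analysis table for the stratified proportional-hazards model:
#' one row per subject per 2-year questionnaire interval at risk. A subject
#' followed without event through all cycles contributes `n_cycles - 1`
#' rows of 2 person-years each; the interval containing the event or
#' censoring time is truncated to that time and later intervals are
#' dropped. Each row carries attained age in single years (the age
#' stratification variable), the interval's exposure quartile — the
#' cumulative-average score through the questionnaire opening the interval,
#' so exposure always precedes outcome — and the time-varying adjustment
#' covariates from that questionnaire.
#'
#' @param cohort Covariate-history table (post [carry_forward()]).
#' @param outcomes Outcome table from [simulate_outcomes()] (or equivalent:
#'   columns `subject_id`, `event`, `event_cycle`, `event_time`, `subtype`,
#'   `censor_cycle`, `censor_time`).
#' @param exposure Exposure assignment from [score_cohort()].
#' @return A tibble, one row per subject-interval: `subject_id`, `cycle`
#'   (interval index), `age_year` (attained age, integer years), `time`
#'   (years at risk within the interval), `event` (0/1, any breast cancer),
#'   `event_erpos`, `event_erneg`, `subtype`, `quartile`, `exposure`, and
#'   the adjustment covariates.
#' @export
expand_person_periods <- function(cohort, outcomes, exposure) {
  if (!all(outcomes$subject_id %in% cohort$subject_id)) {
    stop("outcome table contains subjects absent from the cohort", call. = FALSE)
  }
  last <- outcomes$censor_cycle
  if (any(last < 0)) stop("outcome precedes baseline", call. = FALSE)
  rows <- dplyr::inner_join(
    dplyr::select(cohort, -dplyr::any_of(c("carried_any"))),
    dplyr::select(exposure, "subject_id", "cycle", "exposure", "quartile"),
    by = c("subject_id", "cycle"))
  rows <- dplyr::inner_join(rows, outcomes, by = "subject_id")
  rows <- dplyr::filter(rows, .data$cycle <= .data$censor_cycle)
  final <- rows$cycle == rows$censor_cycle
  rows$time <- ifelse(final, rows$censor_time, 2)
  rows$event <- ifelse(final & rows$event == 1L, 1L, 0L)
  if (any(rows$time <= 0)) {
    # events/censorings at exactly the interval start carry no risk time
    rows$time <- pmax(rows$time, 1e-8)
  }
  rows$subtype[rows$event == 0L] <- NA_character_
  rows$event_erpos <- as.integer(rows$event == 1L &
                                   !is.na(rows$subtype) & rows$subtype == "ER+")
  rows$event_erneg <- as.integer(rows$event == 1L &
                                   !is.na(rows$subtype) & rows$subtype == "ER-")
  rows$age_year <- as.integer(rows$age)
  dplyr::arrange(
    dplyr::select(rows, "subject_id", "cycle", "age_year", "time", "event",
                  "event_erpos", "event_erneg", "subtype", "quartile",
                  "exposure", dplyr::everything(),
                  -dplyr::any_of(c("event_cycle", "event_time",
                                   "censor_cycle", "censor_time", "futime"))),
    .data$subject_id, .data$cycle)
}

# Default multivariable adjustment covariates (the paper-style MV model);
# all must be columns of the person-period table.
mv_covariates <- function() {
  c("parity", "age_first_birth", "age_menarche", "age_menopause_cat",
    "family_history", "oc_recent", "oc_ge10y", "hormone_ep_ge5", "bmi_cat")
}

cox_event_column <- function(outcome) {
  switch(outcome, all = "event", "ER+" = "event_erpos", "ER-" = "event_erneg",
         stop("unknown outcome: ", outcome, call. = FALSE))
}

#' Fit the age/period-stratified proportional-hazards model
#'
#' Estimates incidence rate ratios (IRRs) for exposure quartiles by
#' maximizing the Cox partial likelihood stratified on attained age
#' (single years) x questionnaire cycle, with Efron handling of tied event
#' times, on a counting-process person-period table from
#' [expand_person_periods()]. The highest quartile (4) is the reference;
#' with `exposure_coding = "trend"` the three indicators are replaced by a
#' single ordinal term (quartile number or quartile-median score) whose
#' Wald test is the trend test. Strata without events contribute nothing to
#' the partial likelihood and are dropped by the fitter.
#'
#' Estimation delegates to [survival::coxph()]; the person-period
#' construction, stratification, exposure coding and all downstream
#' summaries are this package's responsibility.
#'
#' @param pp Person-period table.
#' @param outcome `"all"`, `"ER+"` or `"ER-"`. Subtype outcomes censor
#'   events of the other or unknown subtype at their diagnosis time.
#' @param covariates Character vector of adjustment covariate columns;
#'   `NULL` fits the age/period-stratified model with exposure only. Use
#'   `mv_covariates()` for the default multivariable set.
#' @param exposure_coding `"quartile"` (three indicators, quartile 4
#'   reference) or `"trend"` (single ordinal term).
#' @param trend_scores Scores for quartiles 1..4 under trend coding;
#'   default `1:4`, or supply quartile-median scores.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return An object of class `vitd_cox`: `terms` (tibble with `term`,
#'   `log_hr`, `se`, `irr`, `conf_low`, `conf_high`, `p_value`),
#'   `by_quartile` (events and person-years per quartile with IRRs),
#'   `loglik`, `n`, `n_event`, `spec`, and the underlying `fit`.
#' @export
fit_cox <- function(pp, outcome = "all", covariates = mv_covariates(),
                    exposure_coding = c("quartile", "trend"),
                    trend_scores = 1:4, ties = "efron") {
  exposure_coding <- match.arg(exposure_coding)
  evcol <- cox_event_column(outcome)
  if (sum(pp[[evcol]]) < 1L) {
    stop("no events of outcome '", outcome, "' in the person-period table",
         call. = FALSE)
  }
  dat <- pp
  dat$.event <- dat[[evcol]]
  dat$.qfac <- droplevels(factor(dat$quartile, levels = c(4, 3, 2, 1)))
  dat$.qord <- trend_scores[dat$quartile]
  expo_term <- if (exposure_coding == "quartile") ".qfac" else ".qord"
  f <- stats::reformulate(c(expo_term, covariates, "strata(age_year, cycle)"),
                          response = "survival::Surv(time, .event)")
  fit <- survival::coxph(f, data = dat, ties = ties)
  if (!is.null(fit$fail)) {
    stop("proportional-hazards fit failed: ", fit$fail, call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  terms <- tibble::tibble(
    term = rownames(sm),
    log_hr = sm[, "coef"], se = sm[, "se(coef)"],
    irr = exp(sm[, "coef"]),
    conf_low = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
    conf_high = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
    p_value = sm[, "Pr(>|z|)"])
  by_q <- dplyr::summarise(dplyr::group_by(dat, quartile = .data$quartile),
                           events = sum(.data$.event),
                           person_years = sum(.data$time), .groups = "drop")
  by_q <- dplyr::arrange(by_q, dplyr::desc(.data$quartile))
  if (exposure_coding == "quartile") {
    qterms <- paste0(".qfac", by_q$quartile)
    is_ref <- by_q$quartile == 4L
    by_q$irr <- ifelse(is_ref, 1, terms$irr[match(qterms, terms$term)])
    by_q$conf_low <- ifelse(is_ref, NA, terms$conf_low[match(qterms, terms$term)])
    by_q$conf_high <- ifelse(is_ref, NA, terms$conf_high[match(qterms, terms$term)])
  }
  structure(list(terms = terms, by_quartile = by_q,
                 loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_event = fit$nevent,
                 spec = list(outcome = outcome, covariates = covariates,
                             exposure_coding = exposure_coding,
                             trend_scores = trend_scores, ties = ties),
                 fit = fit),
            class = "vitd_cox")
}

#' @export
print.vitd_cox <- function(x, ...) {
  cat(sprintf("<vitd_cox> outcome %s, %s coding, %d events / %d records\n",
              x$spec$outcome, x$spec$exposure_coding, x$n_event, x$n))
  print(x$by_quartile)
  invisible(x)
}

#' @method tidy vitd_cox
#' @export
tidy.vitd_cox <- function(x, ...) x$terms

#' @method glance vitd_cox
#' @export
glance.vitd_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 outcome = x$spec$outcome,
                 exposure_coding = x$spec$exposure_coding)
}

#' Trend test across exposure quartiles
#'
#' Wald test of the single ordinal exposure coefficient in the otherwise
#' identical stratified model: quartiles are replaced by scores (1..4 by
#' default, or quartile medians) and the two-sided p-value of that
#' coefficient is returned. Reversing the score order flips the coefficient
#' sign but leaves the p-value unchanged.
#'
#' @inheritParams fit_cox
#' @return List with `p_value`, `log_hr` (per unit of score), `se`, and the
#'   full `vitd_cox` fit.
#' @export
trend_test <- function(pp, outcome = "all", covariates = mv_covariates(),
                       trend_scores = 1:4, ties = "efron") {
  fit <- fit_cox(pp, outcome = outcome, covariates = covariates,
                 exposure_coding = "trend", trend_scores = trend_scores,
                 ties = ties)
  row <- fit$terms[fit$terms$term == ".qord", ]
  list(p_value = row$p_value, log_hr = row$log_hr, se = row$se, fit = fit)
}

#' Subtype-specific analysis (ER+ / ER-)
#'
#' Fits the same stratified model with events restricted to one estrogen
#' receptor subtype; events of the other subtype and of unknown subtype are
#' censored at their diagnosis time, so no event is ever counted twice
#' across subtype analyses.
#'
#' @inheritParams fit_cox
#' @param subtype `"ER+"` or `"ER-"`.
#' @return A `vitd_cox` object.
#' @export
subtype_analysis <- function(pp, subtype = c("ER+", "ER-"),
                             covariates = mv_covariates(), ties = "efron") {
  subtype <- match.arg(subtype)
  fit_cox(pp, outcome = subtype, covariates = covariates, ties = ties)
}

#' Subgroup analyses within strata of a modifier
#'
#' Fits the stratified model independently within each level of a
#' stratifier and reports per-stratum IRRs. Built-in stratifiers:
#' `"age45"` (attained age < 45 vs >= 45; person-time is split at the row
#' where the 45th birthday falls, so one subject can contribute to both
#' strata), `"supplement"` (current vitamin D supplement use, time-varying),
#' and `"bmi_baseline"` (baseline BMI category, collapsed to < 25,
#' 25-< 30, >= 30; per convention these fits additionally adjust for
#' continuous BMI). Any other column name is used as a row-level stratifier
#' directly. Strata with no events are reported but not fitted.
#'
#' @inheritParams fit_cox
#' @param stratifier Stratifier name (see Details).
#' @return A tibble with one row per stratum: `stratum`, `n_event`, and a
#'   list-column `result` of `vitd_cox` fits (`NULL` where not fitted).
#' @export
subgroup_analysis <- function(pp, stratifier = c("age45", "supplement",
                                                 "bmi_baseline"),
                              covariates = mv_covariates(), ties = "efron") {
  if (length(stratifier) > 1L) stratifier <- match.arg(stratifier)
  covs <- covariates
  if (stratifier == "age45") {
    lev <- ifelse(pp$age_year < 45, "<45", ">=45")
  } else if (stratifier == "supplement") {
    lev <- ifelse(pp$supplement == 1L, "supplement", "no supplement")
  } else if (stratifier == "bmi_baseline") {
    first_rows <- pp[!duplicated(pp$subject_id), c("subject_id", "bmi_cat")]
    base3 <- c("<25" = "<25", "25-29.9" = "25-<30",
               "30-34.9" = ">=30", ">=35" = ">=30")[as.character(first_rows$bmi_cat)]
    lev <- base3[match(pp$subject_id, first_rows$subject_id)]
    covs <- unique(c(setdiff(covariates, "bmi_cat"), "bmi"))
  } else {
    lev <- as.character(pp[[stratifier]])
  }
  evcol <- "event"
  purrr::map_dfr(sort(unique(lev)), function(s) {
    sub <- pp[lev == s, , drop = FALSE]
    nev <- sum(sub[[evcol]])
    res <- if (nev >= 1L) {
      list(fit_cox(sub, outcome = "all", covariates = covs, ties = ties))
    } else {
      list(NULL)
    }
    tibble::tibble(stratum = s, n_event = nev,
                   person_years = sum(sub$time), result = res)
  })
}

#' Likelihood-ratio test for exposure-modifier interaction
#'
#' Compares the stratified model with and without exposure x modifier
#' product terms by likelihood ratio: the statistic is twice the difference
#' in maximized partial log-likelihood, referred to a chi-squared
#' distribution with degrees of freedom equal to the number of product
#' terms. Exposure enters ordinally (trend coding), so the default test has
#' `(levels(modifier) - 1)` degrees of freedom.
#'
#' @inheritParams fit_cox
#' @param modifier Name of a categorical column of `pp`.
#' @return List with `p_value`, `statistic`, `df`, and the two fits.
#' @export
interaction_test <- function(pp, modifier, outcome = "all",
                             covariates = mv_covariates(),
                             trend_scores = 1:4, ties = "efron") {
  evcol <- cox_event_column(outcome)
  dat <- pp
  dat$.event <- dat[[evcol]]
  dat$.qord <- trend_scores[dat$quartile]
  dat$.mod <- factor(dat[[modifier]])
  covs <- setdiff(covariates, modifier)
  base_f <- stats::reformulate(c(".qord", ".mod", covs,
                                 "strata(age_year, cycle)"),
                               response = "survival::Surv(time, .event)")
  int_f <- stats::reformulate(c(".qord * .mod", covs,
                                "strata(age_year, cycle)"),
                              response = "survival::Surv(time, .event)")
  fit0 <- survival::coxph(base_f, data = dat, ties = ties)
  fit1 <- survival::coxph(int_f, data = dat, ties = ties)
  stat <- 2 * (fit1$loglik[2] - fit0$loglik[2])
  df <- length(stats::coef(fit1)) - length(stats::coef(fit0))
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, fit_null = fit0, fit_interaction = fit1)
}
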