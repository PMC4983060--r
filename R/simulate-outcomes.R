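#' Simulate breast-cancer outcomes for a synthetic cohort
#'
#' Draws time-to-event outcomes from a piecewise-constant hazard over the
#' 2-year questionnaire intervals: within the interval starting at cycle
#' `t`, the hazard is `baseline_hazard * exp(quartile_log_hr[q_t] +
#' bmi_log_hr[bmi_cat_t])`, where `q_t` is the subject's exposure quartile
#' at cycle `t`. Event times are exponential within the interval; loss to
#' follow-up occurs independently with probability `ltfu_rate` per interval
#' (censoring uniformly within it); administrative censoring applies at the
#' end of the last interval. Tumour receptor status is drawn from
#' `er_distribution` (joint ER/PR categories), then masked to "unknown"
#' with probability `er_unknown_rate`.
#'
#' @param cohort Covariate histories (post carry-forward, or complete).
#' @param exposure Exposure assignment from [score_cohort()]; must cover
#'   every cohort subject-cycle.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble, one row per subject: `subject_id`, `event` (0/1),
#'   `event_cycle` (interval index of the event), `event_time` (years into
#'   that interval), `receptor_joint` (`ER+/PR+`, `ER+/PR-`, `ER-/PR+`,
#'   `ER-/PR-`, or `NA`), `subtype` (`ER+`, `ER-`, `unknown`, or `NA`),
#'   `censor_cycle`, `censor_time`, `futime` (total follow-up years).
#' @export
simulate_outcomes <- function(cohort, exposure, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else seed
  key <- paste(cohort$subject_id, cohort$cycle)
  q <- exposure$quartile[match(key, paste(exposure$subject_id, exposure$cycle))]
  if (anyNA(q)) {
    stop("exposure assignment does not cover every cohort subject-cycle",
         call. = FALSE)
  }
  n_int <- config$n_cycles - 1L  # risk intervals between questionnaires
  n_subj <- length(unique(cohort$subject_id))
  if (nrow(cohort) != n_subj * config$n_cycles) {
    stop("cohort must contain one row per subject per cycle", call. = FALSE)
  }
  bmi_idx <- as.integer(factor(cohort$bmi_cat, levels = bmi_levels()))
  log_hr <- config$quartile_log_hr[q] + config$bmi_log_hr[bmi_idx]
  hazard <- config$baseline_hazard * exp(log_hr)
  ord <- order(cohort$subject_id, cohort$cycle)
  n <- length(unique(cohort$subject_id))
  haz_mat <- matrix(hazard[ord], nrow = config$n_cycles, ncol = n)[seq_len(n_int), ,
                                                                   drop = FALSE]
  with_seed(spawn_seed(seed, 404L), {
    # exponential event draw per interval; Inf where no event in interval
    u <- matrix(stats::rexp(n_int * n), nrow = n_int)
    t_event <- u / haz_mat               # years into interval
    t_event[t_event > 2] <- Inf
    ltfu <- matrix(stats::runif(n_int * n) < config$ltfu_rate, nrow = n_int)
    t_ltfu <- ifelse(ltfu, matrix(stats::runif(n_int * n, 0, 2), nrow = n_int), Inf)
    # in each interval, whichever of event / LTFU comes first wins; compare
    # on absolute time scale
    abs_event <- sweep(t_event, 1, 2 * (seq_len(n_int) - 1L), "+")
    abs_ltfu <- sweep(t_ltfu, 1, 2 * (seq_len(n_int) - 1L), "+")
    first_abs <- pmin(apply(abs_event, 2, min), apply(abs_ltfu, 2, min),
                      2 * n_int)
    is_event <- apply(abs_event, 2, min) == first_abs & first_abs < 2 * n_int
    cyc <- pmin(floor(first_abs / 2), n_int - 1L)
    within <- first_abs - 2 * cyc
    subj <- sort(unique(cohort$subject_id))
    out <- tibble::tibble(
      subject_id = subj,
      event = as.integer(is_event),
      event_cycle = ifelse(is_event, cyc, NA_integer_),
      event_time = ifelse(is_event, within, NA_real_),
      censor_cycle = as.integer(cyc),
      censor_time = within,
      futime = first_abs)
    k <- sum(out$event)
    rc <- sample(c("ER+/PR+", "ER+/PR-", "ER-/PR+", "ER-/PR-"), k,
                 replace = TRUE, prob = config$er_distribution)
    subtype <- ifelse(startsWith(rc, "ER+"), "ER+", "ER-")
    unknown <- stats::runif(k) < config$er_unknown_rate
    subtype[unknown] <- "unknown"
    out$receptor_joint <- NA_character_
    out$receptor_joint[out$event == 1L] <- ifelse(unknown, NA_character_, rc)
    out$subtype <- NA_character_
    out$subtype[out$event == 1L] <- subtype
    out
  })
}
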