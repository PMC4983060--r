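#' Compute the predicted 25(OH)D score for covariate profiles
#'
#' Applies a coefficient set's *score* terms to one or more covariate
#' profiles: intercept plus the sum of score betas times each indicator or
#' continuous value, in ng/mL. Adjustment terms (season of draw, laboratory,
#' age, UV-B flux) are deliberately excluded — they control variability when
#' the model is estimated but are not part of the cohort score, so a profile
#' with every predictor at its reference level scores exactly the intercept.
#'
#' @param data Data frame with one row per profile, containing the score
#'   predictor columns named in `coeffs`.
#' @param coeffs A [coefficient_set()]; defaults to [vitd_coefficients()].
#' @return Numeric vector of scores (ng/mL), `NA` where a score predictor is
#'   missing (such subject-cycles are flagged unusable downstream).
#' @export
compute_score <- function(data, coeffs = vitd_coefficients()) {
  linear_predictor(data, coeffs, roles = "score", include_intercept = TRUE)
}

#' Carry forward missing questionnaire items
#'
#' Replaces each missing post-baseline questionnaire item with the most
#' recent observed value for the same subject (last observation carried
#' forward). Baseline values must be complete for the items being filled —
#' subjects with missing baseline predictors are excluded from analysis, not
#' imputed — and an informative error is raised otherwise. A logical column
#' `carried_any` records, per subject-cycle, whether any item was filled.
#'
#' @param cohort Covariate-history table (one row per subject-cycle).
#' @param items Character vector of columns to fill; defaults to the
#'   time-varying questionnaire items of the synthetic cohort.
#' @return The cohort table, sorted by subject and cycle, with missing items
#'   filled and `carried_any` appended.
#' @export
carry_forward <- function(cohort, items = intersect(maskable_columns(), names(cohort))) {
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$cycle)
  first <- !duplicated(cohort$subject_id)
  carried <- rep(FALSE, nrow(cohort))
  for (cl in items) {
    v <- cohort[[cl]]
    carried <- carried | is.na(v)
    if (is.factor(v)) {
      lev <- levels(v)
      cohort[[cl]] <- factor(lev[locf_vec(as.integer(v), first)], levels = lev)
    } else {
      cohort[[cl]] <- locf_vec(v, first)
    }
  }
  cohort$carried_any <- carried
  cohort
}

#' Cumulative average of a per-cycle score sequence
#'
#' Element `t` is the mean of elements `1..t`: the exposure at a given cycle
#' is the average of the predicted scores from all cycles up to and
#' including it, smoothing questionnaire-to-questionnaire noise and
#' representing long-term biomarker status.
#'
#' @param scores Non-empty numeric vector, ordered by cycle.
#' @return Numeric vector of running means, same length.
#' @export
cumulative_average <- function(scores) {
  if (length(scores) == 0L) stop("`scores` must be non-empty", call. = FALSE)
  cumsum(scores) / seq_along(scores)
}

#' Simple update of a per-cycle score sequence
#'
#' The sensitivity-analysis exposure: each cycle's exposure is simply that
#' cycle's predicted score (identity mapping), rather than the cumulative
#' average.
#'
#' @inheritParams cumulative_average
#' @return `scores`, unchanged.
#' @export
simple_update <- function(scores) scores

# Running mean within consecutive groups; rows must be sorted by group and
# cycle, with `first` marking each group's first row.
grouped_cumavg <- function(x, first) {
  cs <- cumsum(x)
  start <- which(first)
  len <- diff(c(start, length(x) + 1L))
  offset <- rep(c(0, cs[start[-1L] - 1L]), len)
  (cs - offset) / sequence(len)
}

#' Derive quartile cut points from a score distribution
#'
#' Cut points are the empirical 25th/50th/75th percentiles, computed with
#' the linear-interpolation convention in which the p-th percentile sits at
#' order-statistic position `(n + 1) * p` (`stats::quantile` type 6); a
#' uniform grid `1:100` therefore yields 25.25 / 50.5 / 75.75.
#'
#' @param values Numeric vector with at least 4 distinct values.
#' @param source Free-text description of which distribution the cut points
#'   come from (e.g. "person-time distribution of cumulative-average
#'   scores"), kept for provenance.
#' @return An object of class `quartile_scheme`: list with `cuts` (three
#'   strictly increasing ng/mL values) and `source`.
#' @export
derive_quartiles <- function(values, source = "empirical distribution") {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 4L) {
    stop("quartile derivation needs at least 4 distinct values", call. = FALSE)
  }
  cuts <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  if (any(diff(cuts) <= 0)) {
    stop("degenerate distribution: quartile cut points are not strictly increasing ",
         "(heavy ties)", call. = FALSE)
  }
  structure(list(cuts = cuts, source = source), class = "quartile_scheme")
}

#' @export
print.quartile_scheme <- function(x, ...) {
  cat(sprintf("<quartile_scheme> cuts %.2f / %.2f / %.2f ng/mL (%s)\n",
              x$cuts[1], x$cuts[2], x$cuts[3], x$source))
  invisible(x)
}

#' Assign values to quartiles under a scheme
#'
#' Quartile 1 holds the lowest scores and quartile 4 the highest. A value
#' exactly equal to a cut point goes to the lower quartile.
#'
#' @param values Numeric vector.
#' @param scheme A [derive_quartiles()] result, or three increasing cut
#'   points.
#' @return Integer vector in `1:4` (`NA` for missing values).
#' @export
assign_quartile <- function(values, scheme) {
  cuts <- if (inherits(scheme, "quartile_scheme")) scheme$cuts else scheme
  stopifnot(length(cuts) == 3L, !any(diff(cuts) <= 0))
  1L + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3])
}

#' Score a cohort and assign time-updated exposure quartiles
#'
#' The exposure-engine pipeline stage: carries forward missing items,
#' computes the per-cycle predicted 25(OH)D score from the coefficient
#' set's score terms, forms the per-subject cumulative average (or, for the
#' sensitivity analysis, the simple per-cycle update), derives quartile cut
#' points, and assigns each subject-cycle an exposure quartile.
#'
#' By default the cut points come from the person-time distribution of the
#' exposure over all usable subject-cycles, which makes quartile
#' person-years approximately equal in the subsequent survival analysis.
#' Alternatives: `"baseline"` (cycle-0 distribution) or `"external"`
#' (fixed cut points supplied by the caller).
#'
#' @param cohort Covariate-history table.
#' @param coeffs A [coefficient_set()].
#' @param exposure `"cumulative"` (default) or `"simple"`.
#' @param quartile_source `"person_time"`, `"baseline"` or `"external"`.
#' @param external_cuts Three increasing cut points, required when
#'   `quartile_source = "external"`.
#' @return A tibble, one row per subject-cycle: `subject_id`, `cycle`,
#'   `score` (that cycle's predicted score), `exposure` (cumulative average
#'   or simple update), `quartile`, `carried_any`. The quartile scheme is
#'   attached as attribute `"scheme"`.
#' @export
score_cohort <- function(cohort, coeffs = vitd_coefficients(),
                         exposure = c("cumulative", "simple"),
                         quartile_source = c("person_time", "baseline", "external"),
                         external_cuts = NULL) {
  exposure <- match.arg(exposure)
  quartile_source <- match.arg(quartile_source)
  cohort <- carry_forward(cohort)
  score <- compute_score(cohort, coeffs)
  if (anyNA(score)) {
    stop("missing score predictor remains after carry-forward; ",
         "exclude subjects with incomplete baseline data first", call. = FALSE)
  }
  out <- tibble::tibble(subject_id = cohort$subject_id, cycle = cohort$cycle,
                        score = score, carried_any = cohort$carried_any)
  out <- dplyr::arrange(out, .data$subject_id, .data$cycle)
  out$exposure <- if (exposure == "cumulative") {
    grouped_cumavg(out$score, !duplicated(out$subject_id))
  } else {
    simple_update(out$score)
  }
  scheme <- switch(quartile_source,
    person_time = derive_quartiles(out$exposure,
      source = "person-time distribution of exposure over all subject-cycles"),
    baseline = derive_quartiles(out$exposure[out$cycle == 0L],
      source = "baseline (cycle 0) exposure distribution"),
    external = {
      if (is.null(external_cuts)) {
        stop("`external_cuts` required when quartile_source = 'external'",
             call. = FALSE)
      }
      structure(list(cuts = external_cuts, source = "external cut points"),
                class = "quartile_scheme")
    })
  out$quartile <- assign_quartile(out$exposure, scheme)
  attr(out, "scheme") <- scheme
  out
}
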