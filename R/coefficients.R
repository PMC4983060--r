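#' Construct a 25(OH)D prediction coefficient set
#'
#' A coefficient set is the package's container for a fitted or published
#' linear prediction model for plasma 25-hydroxyvitamin D (ng/mL). It splits
#' terms into two roles: *score* terms, which define the questionnaire-based
#' predicted 25(OH)D score applied to a cohort, and *adjustment* terms
#' (season of blood draw, assay laboratory, age at draw, ambient UV-B flux),
#' which control variability when the model is estimated on a biospecimen
#' panel but are set to their reference level (zero contribution) when the
#' score is computed for cohort members.
#'
#' @param intercept Intercept in ng/mL.
#' @param terms A data frame with columns `term` (display label), `variable`
#'   (column name in a covariate table), `level` (factor level for indicator
#'   terms, `NA` for continuous/binary variables), `beta` (ng/mL per unit or
#'   per indicator), and `role` (`"score"` or `"adjust"`).
#' @param provenance Either `"published"` (coefficients taken from a printed
#'   model) or `"fitted"` (estimated in this session).
#'
#' @return A tibble of class `coef_set` with the intercept and provenance
#'   stored as attributes.
#' @seealso [vitd_coefficients()] for the default published set,
#'   [compute_score()] for applying a set to covariate data.
#' @export
coefficient_set <- function(intercept, terms, provenance = c("fitted", "published")) {
  provenance <- match.arg(provenance)
  stopifnot(is.finite(intercept))
  terms <- tibble::as_tibble(terms)
  needed <- c("term", "variable", "level", "beta", "role")
  if (!all(needed %in% names(terms))) {
    stop("`terms` must have columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!all(terms$role %in% c("score", "adjust"))) {
    stop("term roles must be 'score' or 'adjust'", call. = FALSE)
  }
  if (anyDuplicated(terms$term)) {
    stop("every term must belong to exactly one role; duplicated term labels: ",
         paste(unique(terms$term[duplicated(terms$term)]), collapse = ", "),
         call. = FALSE)
  }
  structure(terms,
            intercept = intercept,
            provenance = provenance,
            class = c("coef_set", class(terms)))
}

#' Default published 25(OH)D prediction coefficients
#'
#' The default coefficient set used throughout the package: the published
#' linear model relating questionnaire covariates to measured plasma 25(OH)D
#' in ng/mL. Score terms: vitamin D supplement use (+9.66), multivitamin use
#' (+4.60), dietary vitamin D (+0.33 per unit), BMI category (-2.21 / -2.96 /
#' -4.71 for 25-29.9 / 30-34.9 / >=35 vs < 25), postmenopausal hormone use
#' (+2.70 past >= 5 y, +2.39 current < 5 y, +2.31 current >= 5 y), vigorous
#' physical activity (+1.59), alcohol (-2.28 for 1-6 drinks/wk, -2.97 for
#' >= 7), current smoking (-1.58), recent oral-contraceptive use (+2.58) and
#' oral-contraceptive use >= 10 years (+1.60), around an intercept of 11.94.
#' Adjustment terms: summer +1.66, winter -1.88, high UV-B flux -1.93, and
#' age +0.24 per year.
#'
#' @return A `coef_set` (see [coefficient_set()]) with `provenance =
#'   "published"`.
#' @export
vitd_coefficients <- function() {
  terms <- tibble::tribble(
    ~term,                      ~variable,            ~level,          ~beta,  ~role,
    "Supplementary vitamin D",  "supplement",         NA,               9.66,  "score",
    "Multivitamin use",         "multivitamin",       NA,               4.60,  "score",
    "Dietary vitamin D",        "dietary_vitd",       NA,               0.33,  "score",
    "BMI 25.0-29.9",            "bmi_cat",            "25-29.9",       -2.21,  "score",
    "BMI 30.0-34.9",            "bmi_cat",            "30-34.9",       -2.96,  "score",
    "BMI >=35.0",               "bmi_cat",            ">=35",          -4.71,  "score",
    "Hormone use, past >=5y",   "hormone_use",        "past_ge5",       2.70,  "score",
    "Hormone use, current <5y", "hormone_use",        "current_lt5",    2.39,  "score",
    "Hormone use, current >=5y","hormone_use",        "current_ge5",    2.31,  "score",
    "Vigorous activity >=1h/wk","vigorous_activity",  NA,               1.59,  "score",
    "Alcohol 1-6/wk",           "alcohol",            "1-6_wk",        -2.28,  "score",
    "Alcohol >=7/wk",           "alcohol",            "ge7_wk",        -2.97,  "score",
    "Current smoking",          "smoking",            NA,              -1.58,  "score",
    "Recent OC use",            "oc_recent",          NA,               2.58,  "score",
    "OC use >=10 years",        "oc_ge10y",           NA,               1.60,  "score",
    "Season: summer",           "season",             "summer",         1.66,  "adjust",
    "Season: winter",           "season",             "winter",        -1.88,  "adjust",
    "UVB flux 160+",            "uvb_high",           NA,              -1.93,  "adjust",
    "Age at draw (years)",      "age_at_draw",        NA,               0.24,  "adjust"
  )
  coefficient_set(intercept = 11.94, terms = terms, provenance = "published")
}

#' @export
print.coef_set <- function(x, ...) {
  cat(sprintf("<coef_set> %s model, intercept %.2f ng/mL\n",
              attr(x, "provenance"), attr(x, "intercept")))
  cat(sprintf("  %d score terms, %d adjustment terms\n",
              sum(x$role == "score"), sum(x$role == "adjust")))
  NextMethod()
  invisible(x)
}

# Linear predictor contribution of one term block, vectorised over rows.
term_contribution <- function(data, variable, level, beta) {
  v <- data[[variable]]
  if (is.null(v)) {
    stop("covariate table lacks column `", variable, "`", call. = FALSE)
  }
  if (is.na(level)) {
    beta * as.numeric(v)
  } else {
    beta * as.numeric(as.character(v) == level)
  }
}

# Sum of contributions for the terms in `coeffs` with the given role(s);
# returns a numeric vector aligned with rows of `data`. NA covariate values
# propagate to NA so callers can flag unusable rows.
linear_predictor <- function(data, coeffs, roles = c("score", "adjust"),
                             include_intercept = TRUE) {
  use <- coeffs[coeffs$role %in% roles, , drop = FALSE]
  out <- rep(if (include_intercept) attr(coeffs, "intercept") else 0, nrow(data))
  for (i in seq_len(nrow(use))) {
    out <- out + term_contribution(data, use$variable[i], use$level[i], use$beta[i])
  }
  out
}
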