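# Biospecimen sub-panel: measured 25(OH)D generated from the prediction
# model's linear predictor plus calibrated residual noise.

# Standardised right-/left-skewed residual: for lambda != 0,
# (exp(lambda * z) - m1) / s1 with z ~ N(0,1), centred and scaled so the
# residual has mean 0 and variance 1 for any lambda. lambda = 0 is the
# Gaussian limit. Skew is the one shape freedom the calibration may use to
# reconcile a fixed variance (set by the R^2 target) with asymmetric
# quartile targets.
skew_residual <- function(z, lambda) {
  if (abs(lambda) < 1e-8) return(z)
  m1 <- exp(lambda^2 / 2)
  s1 <- sqrt((exp(lambda^2) - 1) * exp(lambda^2))
  (exp(lambda * z) - m1) / s1
}

# Assay floor: measured values are reported no lower than 1 ng/mL.
panel_floor <- function(y) pmax(y, 1)

#' Calibrate the biomarker noise model to printed distribution targets
#'
#' Given the linear-predictor values of a panel, chooses the residual noise
#' so that (a) the population proportion of 25(OH)D variance explained by
#' the linear predictor equals `r2_target`, and (b) the marginal quartile
#' cut points of the simulated measured values match `cut_targets`
#' (in quadratic loss). Constraint (a) fixes the residual SD at
#' `sd(lp) * sqrt((1 - r2) / r2)`; the remaining freedom — a location offset
#' and a mild skew in the residual — is fitted to the three cut points with
#' Nelder-Mead. The offset absorbs the difference between the simulated
#' covariate mix and the population the printed cut points describe.
#'
#' @param lp Numeric vector of linear-predictor values (ng/mL).
#' @param z Standard-normal residual draws, same length as `lp`, that will
#'   generate the measured values (calibrating on the very draws used for
#'   output makes the empirical cut points match the targets closely).
#' @param r2_target Proportion of variance explained by `lp`.
#' @param cut_targets Three quartile cut points, ng/mL.
#' @return A list with `sigma` (residual SD), `delta` (location offset,
#'   ng/mL), `lambda` (skew), achieved cut points, and achieved population
#'   R^2.
#' @export
calibrate_panel_noise <- function(lp, z, r2_target = 0.252,
                                  cut_targets = c(21, 31, 40)) {
  stopifnot(length(lp) == length(z), length(cut_targets) == 3L)
  sigma <- stats::sd(lp) * sqrt((1 - r2_target) / r2_target)
  loss <- function(par) {
    y <- panel_floor(lp + par[1] + sigma * skew_residual(z, par[2]))
    q <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
    sum((q - cut_targets)^2)
  }
  start <- c(cut_targets[2] - stats::median(lp), 0)
  fit <- stats::optim(start, loss, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  y <- panel_floor(lp + fit$par[1] + sigma * skew_residual(z, fit$par[2]))
  list(sigma = sigma, delta = fit$par[1], lambda = fit$par[2],
       achieved_cuts = stats::quantile(y, c(0.25, 0.5, 0.75), type = 6,
                                       names = FALSE),
       achieved_r2 = stats::var(lp) / (stats::var(lp) + sigma^2),
       loss = fit$value)
}

#' Sample a measured-25(OH)D biospecimen panel from a synthetic cohort
#'
#' Draws `n_panel` cohort members (their final-cycle questionnaire data,
#' emulating a blood draw shortly after the last questionnaire), assigns a
#' season of draw, an assay laboratory and age at draw, and generates
#' measured 25(OH)D as the full linear predictor — score terms plus season,
#' laboratory and age adjustment terms — plus residual noise.
#'
#' With `residual_sd = NULL` (the default) the noise is calibrated via
#' [calibrate_panel_noise()] so the linear predictor explains
#' `config$r2_target` of the variance and the marginal quartile cut points
#' match `config$quartile_targets`. With an explicit `residual_sd` the noise
#' is plain Gaussian with that SD (0 gives noise-free values equal to the
#' linear predictor).
#'
#' @param cohort Covariate histories from [generate_covariate_histories()]
#'   (complete cases at the final cycle are eligible).
#' @param coeffs A [coefficient_set()]; defaults to [vitd_coefficients()].
#' @param n_panel Panel size; must not exceed the number of eligible
#'   subjects.
#' @param config A [sim_config()] supplying calibration targets, laboratory
#'   effects and the seed.
#' @param residual_sd Optional fixed Gaussian residual SD (ng/mL),
#'   bypassing calibration; overrides `config$residual_sd`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with one row per specimen: `subject_id`,
#'   `measured_25ohd` (ng/mL), `season`, `lab`, `age_at_draw`, the
#'   questionnaire covariates used, and the true linear predictor `lp`.
#'   The calibration result is attached as attribute `"calibration"`.
#' @export
sample_biospecimen_panel <- function(cohort, coeffs = vitd_coefficients(),
                                     n_panel = 2856L, config = sim_config(),
                                     residual_sd = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(residual_sd)) residual_sd <- config$residual_sd
  seed <- if (is.null(seed)) config$seed else seed
  prev <- config$predictor_prevalences
  last_cycle <- max(cohort$cycle)
  eligible <- dplyr::filter(cohort, .data$cycle == last_cycle)
  eligible <- eligible[stats::complete.cases(
    eligible[, intersect(maskable_columns(), names(eligible))]), ]
  if (n_panel > nrow(eligible)) {
    stop("`n_panel` (", n_panel, ") exceeds the ", nrow(eligible),
         " eligible cohort members", call. = FALSE)
  }
  if (!is.null(residual_sd) && residual_sd < 0) {
    stop("`residual_sd` must be non-negative", call. = FALSE)
  }
  with_seed(spawn_seed(seed, 303L), {
    panel <- eligible[sample.int(nrow(eligible), n_panel), , drop = FALSE]
    panel$season <- draw_cat(n_panel, prev$season)
    panel$lab <- factor(sample(1:3, n_panel, replace = TRUE, prob = prev$lab),
                        levels = 1:3)
    panel$age_at_draw <- panel$age
    lab_eff <- prev$lab_effects[as.integer(panel$lab)]
    lp <- linear_predictor(panel, coeffs) + lab_eff
    z <- stats::rnorm(n_panel)
    if (is.null(residual_sd)) {
      cal <- calibrate_panel_noise(lp, z, r2_target = config$r2_target,
                                   cut_targets = config$quartile_targets)
      y <- panel_floor(lp + cal$delta + cal$sigma * skew_residual(z, cal$lambda))
    } else {
      cal <- list(sigma = residual_sd, delta = 0, lambda = 0,
                  achieved_r2 = if (residual_sd == 0) 1 else
                    stats::var(lp) / (stats::var(lp) + residual_sd^2))
      y <- if (residual_sd == 0) lp else panel_floor(lp + residual_sd * z)
    }
    panel$lp <- lp
    panel$measured_25ohd <- y
    out <- dplyr::select(panel, "subject_id", "measured_25ohd", "season",
                         "lab", "age_at_draw", dplyr::everything())
    attr(out, "calibration") <- cal
    tibble::as_tibble(out)
  })
}
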