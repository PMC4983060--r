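# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately written by a different route than the
# package code it checks: explicit loops, closed forms, formula-based lm().

# --- small synthetic fixtures -----------------------------------------------

make_test_panel <- function(n_subjects = 1200, n_panel = 800, seed = 301,
                            n_cycles = 3, ...) {
  cfg <- sim_config(n_subjects = n_subjects, n_cycles = n_cycles,
                    seed = seed, ...)
  cohort <- generate_covariate_histories(cfg)
  sample_biospecimen_panel(cohort, vitd_coefficients(), n_panel = n_panel,
                           config = cfg)
}

make_test_pp <- function(n_subjects = 4000, seed = 11, baseline_hazard = 0.004,
                         n_cycles = 6, ...) {
  cfg <- sim_config(n_subjects = n_subjects, n_cycles = n_cycles, seed = seed,
                    baseline_hazard = baseline_hazard, ...)
  cohort <- generate_covariate_histories(cfg)
  expo <- score_cohort(cohort, vitd_coefficients())
  outcomes <- simulate_outcomes(cohort, expo, cfg)
  expand_person_periods(cohort, outcomes, expo)
}

# A one-row covariate profile with every score predictor at its reference
# level; override individual columns via ...
reference_profile <- function(...) {
  prof <- tibble::tibble(
    supplement = 0L, multivitamin = 0L, dietary_vitd = 0,
    bmi_cat = factor("<25", levels = bmi_levels()),
    hormone_use = factor("none", levels = c("none", "past_ge5", "current_lt5",
                                            "current_ge5")),
    vigorous_activity = 0L,
    alcohol = factor("none", levels = c("none", "1-6_wk", "ge7_wk")),
    smoking = 0L, oc_recent = 0L, oc_ge10y = 0L)
  over <- list(...)
  for (nm in names(over)) prof[[nm]] <- over[[nm]]
  prof
}

# --- Efron partial-likelihood oracle ----------------------------------------

# Explicit enumeration of the stratified Cox partial log-likelihood with
# Efron tie handling, for a person-period table with columns time, .event,
# stratum and a single linear predictor x. Follows the textbook definition:
# within each stratum, for each distinct event time with d tied events,
#   sum_{events} eta_i - sum_{l=0}^{d-1} log( sum_{R} w - (l/d) sum_{D} w )
# where R is the risk set, D the tied events, w = exp(eta).
efron_loglik <- function(beta, time, event, stratum, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (s in unique(stratum)) {
    in_s <- stratum == s
    ts <- time[in_s]; ev <- event[in_s]; es <- eta[in_s]; ws <- w[in_s]
    for (td in sort(unique(ts[ev == 1]))) {
      D <- which(ev == 1 & ts == td)
      R <- which(ts >= td)
      d <- length(D)
      ll <- ll + sum(es[D])
      for (l in seq_len(d) - 1) {
        ll <- ll - log(sum(ws[R]) - (l / d) * sum(ws[D]))
      }
    }
  }
  ll
}

efron_mle <- function(time, event, stratum, x, interval = c(-10, 10)) {
  stats::optimize(function(b) efron_loglik(b, time, event, stratum, x),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# --- brute-force stepwise oracle --------------------------------------------

# Formula-based bidirectional stepwise AIC, independent of the package's
# matrix engine: refits with lm() at every candidate move and recomputes
# the criterion from the residual sum of squares.
brute_stepwise <- function(data, candidates, forced, response) {
  aic_of <- function(vars) {
    f <- stats::reformulate(c(forced, vars), response = response)
    fit <- stats::lm(f, data = data)
    rss <- sum(stats::residuals(fit)^2)
    k <- length(stats::coef(fit))
    nrow(data) * log(rss / nrow(data)) + 2 * (k + 1)
  }
  active <- character(0)
  cur <- aic_of(active)
  repeat {
    moves <- c(lapply(active, function(v) setdiff(active, v)),
               lapply(setdiff(candidates, active), function(v) c(active, v)))
    if (!length(moves)) break
    aics <- vapply(moves, aic_of, numeric(1))
    best <- which.min(aics)
    if (!(aics[best] < cur - 1e-8)) break
    active <- moves[[best]]
    cur <- aics[best]
  }
  list(selected = sort(active), aic = cur)
}
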