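#' Random k-fold partition
#'
#' Assigns `n` observations to `k` disjoint folds of as-equal-as-possible
#' size (sizes differ by at most one), uniformly at random given the seed.
#'
#' @param n Number of observations (>= k).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Integer vector of fold labels in `1:k`, length `n`.
#' @export
kfold_partition <- function(n, k, seed = NULL) {
  n <- assert_count(n, "n"); k <- assert_count(k, "k", min = 2L)
  if (k > n) stop("`k` must not exceed `n`", call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Quartile cross-classification agreement
#'
#' Classifies two equal-length vectors into their own empirical quartiles
#' (each vector's quartiles computed separately, with the [derive_quartiles()]
#' convention) and cross-tabulates them. The diagonal fraction is the
#' same-quartile agreement; adding the first off-diagonals gives the
#' same-or-adjacent agreement.
#'
#' @param observed,predicted Numeric vectors of equal length, n >= 4.
#' @return List with `same` and `same_or_adjacent` fractions and `matrix`,
#'   the 4 x 4 observed-by-predicted proportion matrix (entries sum to 1).
#' @export
quartile_agreement <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 4L) stop("need n >= 4 for quartiles", call. = FALSE)
  qo <- tryCatch(assign_quartile(observed, derive_quartiles(observed)),
                 error = function(e) stop(
                   "observed vector: quartiles undefined (heavy ties)",
                   call. = FALSE))
  qp <- tryCatch(assign_quartile(predicted, derive_quartiles(predicted)),
                 error = function(e) stop(
                   "predicted vector: quartiles undefined (heavy ties)",
                   call. = FALSE))
  tab <- table(factor(qo, 1:4), factor(qp, 1:4)) / length(observed)
  list(same = sum(diag(tab)),
       same_or_adjacent = sum(tab[abs(row(tab) - col(tab)) <= 1]),
       matrix = unclass(tab))
}

#' Repeated k-fold cross-validation of the 25(OH)D prediction model
#'
#' The model-derivation loop: for each of `reps` random partitions of the
#' panel into `k` folds, each fold in turn is held out while stepwise-AIC
#' selection ([stepwise_select()]) and least-squares fitting run on the
#' remaining folds; the fitted model predicts the held-out fold, and the
#' Pearson correlation between observed and predicted values plus their
#' quartile cross-classification are recorded. Held-out predictions use the
#' full linear predictor — adjustment covariates (season, laboratory, age)
#' at their observed values — since the correlation is a model-fit
#' diagnostic; a score-only correlation (adjusters at reference) is also
#' recorded as `r_score`.
#'
#' @param data The biospecimen panel: complete cases on the response and all
#'   candidate/forced variables.
#' @param candidates A [candidate_spec()].
#' @param k Folds per repetition (default 5).
#' @param reps Number of random re-partitions (default 100).
#' @param seed Master seed; per-repetition partition seeds are derived from
#'   it.
#' @param response Response column name.
#' @param return_predictions Keep the held-out predictions (one numeric
#'   vector per repetition, aligned with rows of `data`) in the result;
#'   useful for leave-one-out checks.
#' @return An object of class `cv_performance`: `mean_r` (mean test-fold
#'   Pearson correlation over all folds and repetitions), `sd_r` (SD of the
#'   per-repetition mean correlations), `mean_r2` (mean squared test-fold
#'   correlation), `same_quartile` and `same_or_adjacent` (pooled agreement
#'   fractions), `agreement` (pooled 4 x 4 proportion matrix), `per_fold`
#'   (tibble of per-fold records), `selection_freq` (fraction of folds in
#'   which each candidate was retained), and the settings used.
#' @export
repeated_cv <- function(data, candidates = default_candidates(), k = 5L,
                        reps = 100L, seed = 1L,
                        response = "measured_25ohd",
                        return_predictions = FALSE) {
  k <- assert_count(k, "k", min = 2L)
  reps <- assert_count(reps, "reps")
  d <- build_design(data, candidates, response)
  n <- nrow(d$X)
  score_cols <- sort(c(1L, unlist(d$blocks, use.names = FALSE)))
  per_fold <- vector("list", reps * k)
  predictions <- if (return_predictions) vector("list", reps) else NULL
  agree_sum <- matrix(0, 4, 4)
  sel_count <- stats::setNames(numeric(length(d$blocks)), names(d$blocks))
  idx <- 0L
  for (r in seq_len(reps)) {
    fold <- kfold_partition(n, k, seed = spawn_seed(seed, 1000L + r))
    if (return_predictions) predictions[[r]] <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- fold == f
      y_test <- d$y[test]
      if (length(unique(d$y[!test])) < 2L) {
        stop("degenerate fold: fewer than 2 distinct response values",
             call. = FALSE)
      }
      sw <- stepwise_engine(d$X[!test, , drop = FALSE], d$y[!test],
                            d$blocks, d$forced_cols)
      sel_count[sw$selected] <- sel_count[sw$selected] + 1
      pred <- drop(d$X[test, sw$cols, drop = FALSE] %*% sw$coef)
      if (return_predictions) predictions[[r]][test] <- pred
      keep_score <- sw$cols %in% score_cols
      pred_score <- drop(d$X[test, sw$cols[keep_score], drop = FALSE] %*%
                           sw$coef[keep_score])
      # in-sample fit of the selected model, for shrinkage diagnostics
      r2_train <- 1 - sw$rss / sum((d$y[!test] - mean(d$y[!test]))^2)
      r_full <- if (length(y_test) >= 2L) stats::cor(y_test, pred) else NA_real_
      ag <- if (length(y_test) >= 4L) quartile_agreement(y_test, pred)
            else list(same = NA_real_, same_or_adjacent = NA_real_,
                      matrix = matrix(0, 4, 4))
      agree_sum <- agree_sum + ag$matrix
      idx <- idx + 1L
      per_fold[[idx]] <- tibble::tibble(
        rep = r, fold = f, r = r_full, r2 = r_full^2,
        r_score = if (length(y_test) >= 2L) stats::cor(y_test, pred_score)
                  else NA_real_,
        r2_train = r2_train,
        same_quartile = ag$same, same_or_adjacent = ag$same_or_adjacent,
        n_selected = length(sw$selected),
        selected = paste(sw$selected, collapse = ";"))
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  rep_means <- dplyr::summarise(dplyr::group_by(per_fold, .data$rep),
                                mean_r = mean(.data$r), .groups = "drop")
  structure(list(
    mean_r = mean(per_fold$r),
    sd_r = stats::sd(rep_means$mean_r),
    mean_r2 = mean(per_fold$r2),
    mean_r_score = mean(per_fold$r_score),
    same_quartile = mean(per_fold$same_quartile),
    same_or_adjacent = mean(per_fold$same_or_adjacent),
    agreement = agree_sum / (reps * k),
    per_fold = per_fold,
    predictions = predictions,
    selection_freq = sel_count / (reps * k),
    settings = list(k = k, reps = reps, seed = seed, n = n,
                    response = response)),
    class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, ...) {
  cat(sprintf("<cv_performance> %d x %d-fold cross-validation, n = %d\n",
              x$settings$reps, x$settings$k, x$settings$n))
  cat(sprintf("  mean test-fold r     %.3f (SD of repetition means %.3f)\n",
              x$mean_r, x$sd_r))
  cat(sprintf("  mean test-fold R^2   %.3f\n", x$mean_r2))
  cat(sprintf("  same quartile        %.1f%%\n", 100 * x$same_quartile))
  cat(sprintf("  same or adjacent     %.1f%%\n", 100 * x$same_or_adjacent))
  invisible(x)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' @method tidy cv_performance
#' @export
tidy.cv_performance <- function(x, ...) x$per_fold

#' @method glance cv_performance
#' @export
glance.cv_performance <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, sd_r = x$sd_r, mean_r2 = x$mean_r2,
                 same_quartile = x$same_quartile,
                 same_or_adjacent = x$same_or_adjacent,
                 k = x$settings$k, reps = x$settings$reps, n = x$settings$n)
}

#' Derive the prediction model on the full panel
#'
#' Runs stepwise-AIC selection on the full biospecimen panel, fits the
#' final model, and packages the result as a [coefficient_set()] (selected
#' questionnaire predictors as score terms; season, laboratory, age and
#' UV-B flux as adjustment terms) together with a report table in the
#' conventional layout — beta, Wald p-value and squared semi-partial
#' correlation per term.
#'
#' @inheritParams repeated_cv
#' @param adjust_role Variables that, if selected, are treated as adjustment
#'   rather than score terms when the coefficient set is applied to a
#'   cohort (ambient UV-B flux by default, since residence-based sun
#'   exposure is controlled in the regression but not part of the
#'   questionnaire score).
#' @return An object of class `vitd_model`: `coef_set`, `report` (tibble:
#'   term, variable, role, beta, p_value, semipartial_pct), `selected`,
#'   `adj_r2`, `stepwise` (the [stepwise_select()] result).
#' @export
fit_prediction_model <- function(data, candidates = default_candidates(),
                                 response = "measured_25ohd",
                                 adjust_role = "uvb_high") {
  sw <- stepwise_select(data, candidates, response)
  d <- build_design(data, candidate_spec(sw$selected,
                                         candidates$forced_adjusters),
                    response)
  fit <- sw$fit
  labels <- attr(stats::terms(d$formula), "term.labels")
  assign <- attr(d$X, "assign")
  cols <- colnames(d$X)
  keep <- which(cols %in% names(fit$coefficients) & assign > 0L)
  term_var <- labels[assign[keep]]
  term_level <- vapply(seq_along(keep), function(i) {
    v <- data[[term_var[i]]]
    if (is.factor(v)) sub(term_var[i], "", cols[keep[i]], fixed = TRUE)
    else NA_character_
  }, character(1))
  role <- ifelse(term_var %in% candidates$forced_adjusters |
                   term_var %in% adjust_role, "adjust", "score")
  terms_tbl <- tibble::tibble(
    term = cols[keep], variable = term_var, level = term_level,
    beta = as.numeric(fit$coefficients[cols[keep]]), role = role)
  cs <- coefficient_set(intercept = fit$coefficients[["(Intercept)"]],
                        terms = terms_tbl, provenance = "fitted")
  sp <- semipartial_r2(data, terms = sw$selected, candidates = candidates,
                       response = response)
  sp_by_var <- stats::setNames(sp$semipartial_pct, sp$term)
  report <- dplyr::mutate(terms_tbl,
    p_value = as.numeric(fit$p_value[.data$term]),
    semipartial_pct = as.numeric(sp_by_var[.data$variable]))
  structure(list(coef_set = cs, report = report, selected = sw$selected,
                 adj_r2 = fit$adj_r2, stepwise = sw),
            class = "vitd_model")
}

#' @export
print.vitd_model <- function(x, ...) {
  cat(sprintf("<vitd_model> stepwise-selected prediction model, adj R^2 = %.3f\n",
              x$adj_r2))
  cat(sprintf("  intercept %.2f ng/mL; %d terms\n",
              attr(x$coef_set, "intercept"), nrow(x$report)))
  print(x$report, n = Inf)
  invisible(x)
}

#' @method tidy vitd_model
#' @export
tidy.vitd_model <- function(x, ...) x$report

#' @method glance vitd_model
#' @export
glance.vitd_model <- function(x, ...) {
  tibble::tibble(adj_r2 = x$adj_r2, n_selected = length(x$selected),
                 aic = x$stepwise$aic)
}
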