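#' Candidate predictors and forced adjusters for model derivation
#'
#' Defines the variable pool over which stepwise selection runs: the
#' questionnaire-based *score candidates* (supplement use, multivitamin use,
#' dietary vitamin D, BMI as category and as a continuous term, vigorous
#' exercise, walking, smoking, alcohol, female hormone use, oral
#' contraceptives, menopausal status, ambient UV-B flux) and the *forced
#' adjusters* — season of blood draw, assay laboratory, and age at draw —
#' which are always in the model and never eligible for removal. Categorical
#' variables enter and leave as whole blocks; encodings (reference levels)
#' are taken from the factor levels of the data.
#'
#' @param score_candidates Character vector of candidate variable names.
#' @param forced_adjusters Character vector of adjuster variable names;
#'   must be disjoint from the candidates.
#' @return A list of class `candidate_spec`.
#' @export
candidate_spec <- function(score_candidates, forced_adjusters) {
  if (length(intersect(score_candidates, forced_adjusters))) {
    stop("forced adjusters must be disjoint from score candidates", call. = FALSE)
  }
  structure(list(score_candidates = score_candidates,
                 forced_adjusters = forced_adjusters),
            class = "candidate_spec")
}

#' @rdname candidate_spec
#' @export
default_candidates <- function() {
  candidate_spec(
    score_candidates = c("supplement", "multivitamin", "dietary_vitd",
                         "bmi_cat", "bmi", "hormone_use", "vigorous_activity",
                         "walking", "alcohol", "smoking", "oc_recent",
                         "oc_ge10y", "menopausal", "uvb_high"),
    forced_adjusters = c("season", "lab", "age_at_draw"))
}

# Model-matrix machinery shared by the fitting, stepwise and CV code.
# Builds the full design once and records, per variable, which columns form
# its block, so stepwise moves are column-subset least-squares problems.
build_design <- function(data, candidates, response = "measured_25ohd") {
  vars <- c(candidates$score_candidates, candidates$forced_adjusters)
  missing_vars <- setdiff(c(vars, response), names(data))
  if (length(missing_vars)) {
    stop("data lacks columns: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  f <- stats::reformulate(vars, response = response)
  mf <- stats::model.frame(f, data, na.action = stats::na.fail)
  X <- stats::model.matrix(f, mf)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(f), "term.labels")
  blocks <- lapply(seq_along(labels), function(i) which(assign == i))
  names(blocks) <- labels
  forced_cols <- c(which(assign == 0L),
                   unlist(blocks[candidates$forced_adjusters], use.names = FALSE))
  list(X = X, y = stats::model.response(mf),
       blocks = blocks[candidates$score_candidates],
       forced_cols = forced_cols, formula = f)
}

# Least squares on selected columns; returns rss, coefficients and rank.
ls_fit <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  coefs <- fit$coefficients
  # .lm.fit pivots columns; restore original order
  coefs[fit$pivot] <- fit$coefficients
  list(rss = rss, coef = coefs, rank = fit$rank)
}

#' Gaussian AIC from a residual sum of squares
#'
#' `AIC = n * log(rss / n) + 2 * (k + 1)`, where `k` is the number of mean
#' parameters (regression coefficients including the intercept) and the
#' `+ 1` counts the error variance. The additive `2*pi` constant of the full
#' Gaussian log-likelihood is omitted; only AIC differences matter and every
#' comparison in this package uses this same convention. A perfect fit
#' (`rss = 0`) returns `-Inf` so it dominates any comparison.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of observations (> k).
#' @param k Number of regression coefficients (>= 1).
#' @return The AIC value.
#' @export
aic_gaussian <- function(rss, n, k) {
  stopifnot(n > k, k >= 1, rss >= 0)
  if (rss == 0) return(-Inf)
  n * log(rss / n) + 2 * (k + 1)
}

#' Fit a linear model by least squares
#'
#' Ordinary least squares for a fully specified design (no selection). The
#' design must include an intercept column and have more rows than columns;
#' a rank-deficient design is rejected with the offending collinear columns
#' named.
#'
#' @param design Numeric matrix or data frame of predictors, including an
#'   intercept column; no missing entries.
#' @param response Numeric response vector (ng/mL in the biomarker
#'   application).
#' @return A list of class `vitd_lm`: `coefficients` (named), `rss`,
#'   `sigma2`, `r2`, `adj_r2`, `se` (coefficient standard errors),
#'   `p_value` (Wald t-tests), `n`, `k`, `df_residual`.
#' @export
fit_linear_model <- function(design, response) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  if (anyNA(X) || anyNA(y)) stop("design and response must be complete", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more rows than columns", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < k) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):k]]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrx, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- coefs / se
  structure(list(coefficients = stats::setNames(as.numeric(coefs), colnames(X)),
                 rss = rss, sigma2 = sigma2,
                 r2 = 1 - rss / tss,
                 adj_r2 = 1 - (rss / (n - k)) / (tss / (n - 1)),
                 se = stats::setNames(se, colnames(X)),
                 p_value = stats::setNames(
                   2 * stats::pt(abs(tval), n - k, lower.tail = FALSE), colnames(X)),
                 n = n, k = k, df_residual = n - k),
            class = "vitd_lm")
}

# Core bidirectional stepwise search on a prebuilt design. Starts from the
# forced-only model; at each step evaluates every single add (inactive
# block) and drop (active block), takes the move with the lowest AIC, and
# stops when no move strictly lowers the criterion. Equal-AIC ties are
# broken toward the smaller model (drops before adds, then fewer columns).
stepwise_engine <- function(X, y, blocks, forced_cols, trace = FALSE) {
  n <- nrow(X)
  active <- character(0)
  cur_cols <- sort(forced_cols)
  cur <- ls_fit(X[, cur_cols, drop = FALSE], y)
  cur_aic <- aic_gaussian(cur$rss, n, length(cur_cols))
  path <- list(list(move = "start", term = NA_character_, aic = cur_aic))
  repeat {
    cand_moves <- rbind(
      if (length(active))
        data.frame(move = "drop", term = active, stringsAsFactors = FALSE),
      if (length(setdiff(names(blocks), active)))
        data.frame(move = "add", term = setdiff(names(blocks), active),
                   stringsAsFactors = FALSE))
    if (is.null(cand_moves) || nrow(cand_moves) == 0L) break
    aics <- vapply(seq_len(nrow(cand_moves)), function(i) {
      term <- cand_moves$term[i]
      new_active <- if (cand_moves$move[i] == "add") c(active, term)
                    else setdiff(active, term)
      cols <- sort(c(forced_cols, unlist(blocks[new_active], use.names = FALSE)))
      fit <- ls_fit(X[, cols, drop = FALSE], y)
      if (fit$rank < length(cols)) return(Inf)
      aic_gaussian(fit$rss, n, length(cols))
    }, numeric(1))
    # ties toward the smaller model: drops are listed first and which.min
    # takes the first minimum
    best <- which.min(aics)
    if (!(aics[best] < cur_aic - 1e-8)) break
    term <- cand_moves$term[best]
    active <- if (cand_moves$move[best] == "add") c(active, term)
              else setdiff(active, term)
    cur_aic <- aics[best]
    path <- c(path, list(list(move = cand_moves$move[best], term = term,
                              aic = cur_aic)))
    if (trace) message(sprintf("%s %s -> AIC %.3f", cand_moves$move[best],
                               term, cur_aic))
  }
  cols <- sort(c(forced_cols, unlist(blocks[active], use.names = FALSE)))
  fit <- ls_fit(X[, cols, drop = FALSE], y)
  list(selected = active, cols = cols,
       coef = stats::setNames(fit$coef, colnames(X)[cols]),
       rss = fit$rss, aic = cur_aic,
       path = dplyr::bind_rows(lapply(path, tibble::as_tibble)))
}

#' Bidirectional stepwise selection by AIC
#'
#' Selects questionnaire predictors of the response by bidirectional
#' stepwise search under the Gaussian AIC of [aic_gaussian()], starting from
#' the model containing only the forced adjusters. Forced adjusters are
#' always retained and never eligible for removal; categorical variables
#' move as whole blocks; the search stops when no single addition or removal
#' lowers the AIC, and is deterministic given the data. An empty candidate
#' list returns the forced-only model.
#'
#' @param data Data frame containing the response and all candidate/forced
#'   variables, complete cases only.
#' @param candidates A [candidate_spec()].
#' @param response Name of the response column.
#' @return A list of class `vitd_stepwise`: `selected` (candidate variables
#'   retained, in order of entry), `coefficients`, `rss`, `aic`, `path`
#'   (tibble of accepted moves with the AIC trace), and `fit` (a
#'   [fit_linear_model()] object for the final model).
#' @export
stepwise_select <- function(data, candidates = default_candidates(),
                            response = "measured_25ohd") {
  d <- build_design(data, candidates, response)
  res <- stepwise_engine(d$X, d$y, d$blocks, d$forced_cols)
  fit <- fit_linear_model(d$X[, res$cols, drop = FALSE], d$y)
  structure(list(selected = res$selected, coefficients = res$coef,
                 rss = res$rss, aic = res$aic, path = res$path, fit = fit,
                 candidates = candidates, response = response),
            class = "vitd_stepwise")
}

#' @export
print.vitd_stepwise <- function(x, ...) {
  cat("<vitd_stepwise> AIC", format(x$aic, digits = 6), "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
                     else "(forced-only model)", "\n")
  invisible(x)
}

#' Squared semi-partial correlations (variance decomposition)
#'
#' For each term in the model, the squared semi-partial correlation is the
#' drop in model R-squared when that term (the whole block, for categorical
#' variables) is removed and the model refitted — the share of total
#' response variation attributable to the term after adjusting for all
#' others — expressed in percent. Score terms and forced adjusters are both
#' decomposed; the `role` column separates them, mirroring the convention of
#' reporting adjusters beneath the score predictors.
#'
#' @param data Data frame with response and covariates.
#' @param terms Character vector of score variables in the model (defaults
#'   to all candidates of `candidates`).
#' @param candidates A [candidate_spec()] supplying forced adjusters.
#' @param response Response column name.
#' @return A tibble: `term`, `role`, `semipartial_pct`, ordered as supplied.
#' @export
semipartial_r2 <- function(data, terms = NULL,
                           candidates = default_candidates(),
                           response = "measured_25ohd") {
  if (is.null(terms)) terms <- candidates$score_candidates
  spec <- candidate_spec(terms, candidates$forced_adjusters)
  d <- build_design(data, spec, response)
  tss <- sum((d$y - mean(d$y))^2)
  r2_of <- function(cols) {
    f <- ls_fit(d$X[, sort(cols), drop = FALSE], d$y)
    1 - f$rss / tss
  }
  all_cols <- c(d$forced_cols, unlist(d$blocks, use.names = FALSE))
  r2_full <- r2_of(all_cols)
  drop_one <- function(block_cols) r2_full - r2_of(setdiff(all_cols, block_cols))
  score_sp <- vapply(d$blocks, drop_one, numeric(1))
  # adjusters: same refit-and-difference, dropping each forced block
  f_assign <- attr(d$X, "assign")
  labels <- attr(stats::terms(d$formula), "term.labels")
  adj_sp <- vapply(stats::setNames(spec$forced_adjusters, spec$forced_adjusters),
                   function(adj) drop_one(which(f_assign == match(adj, labels))),
                   numeric(1))
  tibble::tibble(
    term = c(names(score_sp), names(adj_sp)),
    role = c(rep("score", length(score_sp)), rep("adjust", length(adj_sp))),
    semipartial_pct = 100 * unname(c(score_sp, adj_sp)))
}
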