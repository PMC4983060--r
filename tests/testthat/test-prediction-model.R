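test_that("least squares recovers exact and closed-form solutions", {
  set.seed(1)
  X <- cbind(1, matrix(rnorm(50 * 3), 50, 3))
  colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
  beta <- c(2, -1, 0.5, 3)
  fit <- fit_linear_model(X, drop(X %*% beta))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)

  y <- rnorm(30, 10)
  fit0 <- fit_linear_model(matrix(1, 30, 1, dimnames = list(NULL, "int")), y)
  expect_equal(unname(fit0$coefficients), mean(y))

  # normal-equations oracle on a random 50 x 4 problem
  y <- drop(X %*% beta) + rnorm(50)
  fit <- fit_linear_model(X, y)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(oracle)), tolerance = 1e-8)

  # rank deficiency is reported with the offending column
  Xbad <- cbind(X, dup = X[, "x1"])
  expect_error(fit_linear_model(Xbad, y), "dup")
})

test_that("the Gaussian AIC convention is internally consistent", {
  expect_equal(aic_gaussian(rss = 100, n = 100, k = 2), 6)
  # a coefficient that buys no fit costs exactly 2
  expect_equal(aic_gaussian(50, 200, 5) + 2, aic_gaussian(50, 200, 6))
  expect_identical(aic_gaussian(0, 10, 2), -Inf)
  # equals -2 * max Gaussian log-likelihood + 2(k+1), up to the constant
  # n * (1 + log(2*pi)) that the convention drops
  set.seed(2)
  y <- rnorm(40); X <- cbind(1, rnorm(40))
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  ll <- sum(stats::dnorm(stats::lm.fit(X, y)$residuals, 0,
                         sqrt(rss / 40), log = TRUE))
  expect_equal(aic_gaussian(rss, 40, 2),
               -2 * ll + 2 * 3 - 40 * (1 + log(2 * pi)),
               tolerance = 1e-8)
})

test_that("stepwise returns the forced-only model for empty candidates and never increases AIC", {
  panel <- make_test_panel(n_subjects = 600, n_panel = 400, seed = 17)
  empty <- candidate_spec(character(0), c("season", "lab", "age_at_draw"))
  sw <- stepwise_select(panel, empty)
  expect_identical(sw$selected, character(0))
  expect_setequal(names(sw$coefficients),
                  c("(Intercept)", "seasonwinter", "seasonother",
                    "lab2", "lab3", "age_at_draw"))

  full <- stepwise_select(panel)
  expect_true(all(diff(full$path$aic) <= 1e-8))
  expect_gt(length(full$selected), 2)
})

test_that("a strong predictor is essentially always selected", {
  set.seed(5)
  hits <- vapply(1:25, function(i) {
    d <- tibble::tibble(x = rnorm(500), junk = rnorm(500),
                        y = 10 * x + rnorm(500))  # beta = 10 x residual SD
    sw <- stepwise_select(d, candidate_spec(c("x", "junk"), character(0)),
                          response = "y")
    "x" %in% sw$selected
  }, logical(1))
  expect_true(all(hits))
})

test_that("stepwise agrees with an independent brute-force implementation", {
  set.seed(8)
  for (i in 1:15) {
    n <- 120
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n),
      x5 = rnorm(n), g = factor(sample(c("a", "b", "c"), n, TRUE)),
      adj = rnorm(n))
    d$y <- 0.4 * d$x1 + 0.25 * (d$g == "b") + 0.3 * d$adj + rnorm(n)
    mine <- stepwise_select(d, candidate_spec(c("x1", "x2", "x3", "x4", "x5", "g"),
                                              "adj"), response = "y")
    oracle <- brute_stepwise(d, c("x1", "x2", "x3", "x4", "x5", "g"),
                             "adj", "y")
    expect_identical(sort(mine$selected), oracle$selected)
    expect_equal(mine$aic, oracle$aic, tolerance = 1e-6)
  }
})

test_that("semi-partial R2 equals the refit-and-difference oracle and is order-invariant", {
  panel <- make_test_panel(n_subjects = 900, n_panel = 600, seed = 23)
  terms <- c("supplement", "multivitamin", "bmi_cat", "smoking")
  sp <- semipartial_r2(panel, terms = terms)
  # oracle: formula-based lm refits
  r2_lm <- function(vars) {
    summary(stats::lm(stats::reformulate(c(vars, "season", "lab", "age_at_draw"),
                                         "measured_25ohd"), data = panel))$r.squared
  }
  for (tm in terms) {
    expect_equal(sp$semipartial_pct[sp$term == tm],
                 100 * (r2_lm(terms) - r2_lm(setdiff(terms, tm))),
                 tolerance = 1e-8)
  }
  sp_rev <- semipartial_r2(panel, terms = rev(terms))
  expect_equal(sp$semipartial_pct[match(sp_rev$term, sp$term)],
               sp_rev$semipartial_pct, tolerance = 1e-10)

  # orthogonal predictors: semi-partial equals marginal R2
  set.seed(3)
  n <- 400
  x1 <- rep(c(-1, 1), n / 2); x2 <- rep(c(-1, 1), each = n / 2)  # orthogonal
  d <- tibble::tibble(x1 = x1, x2 = x2, y = x1 + 0.5 * x2 + rnorm(n))
  sp2 <- semipartial_r2(d, terms = c("x1", "x2"),
                        candidates = candidate_spec(c("x1", "x2"), character(0)),
                        response = "y")
  marg <- function(v) summary(stats::lm(stats::reformulate(v, "y"), d))$r.squared
  expect_equal(sp2$semipartial_pct[sp2$term == "x1"], 100 * marg("x1"),
               tolerance = 1e-6)
  expect_equal(sp2$semipartial_pct[sp2$term == "x2"], 100 * marg("x2"),
               tolerance = 1e-6)
  # a pure-noise term contributes essentially nothing
  d$junk <- rnorm(n)
  sp3 <- semipartial_r2(d, terms = c("x1", "x2", "junk"),
                        candidates = candidate_spec(c("x1", "x2", "junk"),
                                                    character(0)),
                        response = "y")
  expect_lt(sp3$semipartial_pct[sp3$term == "junk"], 1)
})
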