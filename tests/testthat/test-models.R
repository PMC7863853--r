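# A classified, scored wave used across the model tests.
model_data <- function(n = 800L, seed = 14L, ...) {
  p <- generate_panel(generator_config(n_wave2 = n, seed = seed, ...))
  d <- as.data.frame(p$wave2)
  d$impact_score <- covid_impact_score(d)$impact_score
  d$emotion_score <- emotion_score(d)
  d$worry_group <- droplevels(classify_full(d)$worry_group)
  d
}

test_that("pca block scores: rank-1 block, sign equivariance, standardisation", {
  set.seed(2)
  x <- rnorm(200)
  # two perfectly correlated items: scores equal the standardised item (up to sign)
  s <- pca_block_score(cbind(a = 2 * x + 1, b = 5 * x - 3))
  expect_equal(abs(cor(s, x)), 1, tolerance = 1e-12)
  expect_equal(mean(s), 0, tolerance = 1e-6)
  expect_equal(stats::var(s), 1, tolerance = 1e-6)
  m <- matrix(rnorm(200 * 3), ncol = 3)
  s1 <- pca_block_score(m)
  s2 <- pca_block_score(-m)
  expect_equal(as.numeric(s2), -as.numeric(s1))
  # orthogonal-by-construction items: first component explains ~ 1/k (the
  # top eigenvalue of a k x k sample correlation matrix sits slightly above
  # 1 at finite n, within the Marchenko-Pastur edge ~ (1 + sqrt(k/n))^2)
  big <- matrix(rnorm(20000 * 4), ncol = 4)
  expect_lt(abs(attr(pca_block_score(big), "prop_var") - 0.25), 0.02)
  expect_error(pca_block_score(cbind(rep(1, 10), rnorm(10))), "zero-variance")
})

test_that("multinomial fits report exponentiated ratios with per-row probabilities summing to 1", {
  d <- model_data()
  spec <- model_spec("multinomial_logit", "worry_group", c("had_covid", "impact_score"),
                     reference_outcome = "unworried")
  res <- fit_model(spec, d)
  expect_true(all(res$estimate > 0))
  expect_true(all(res$conf_low <= res$conf_high))
  expect_lte(attr(res, "n"), nrow(d))
  pr <- stats::fitted(attr(res, "fit"))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-10))
})

test_that("switching the multinomial reference category is self-consistent", {
  d <- model_data(n = 600L, seed = 15L)
  spec_u <- model_spec("multinomial_logit", "worry_group", c("had_covid", "impact_score"),
                       reference_outcome = "unworried")
  spec_d <- model_spec("multinomial_logit", "worry_group", c("had_covid", "impact_score"),
                       reference_outcome = "dysfunctional")
  ru <- as.data.frame(fit_model(spec_u, d))
  rd <- as.data.frame(fit_model(spec_d, d))
  pick <- function(r, lv, tm) r$estimate[r$outcome_level == lv & r$term == tm]
  for (tm in c("had_covidyes", "impact_score")) {
    # log(F/U) - log(D/U) = log(F/D)
    expect_equal(pick(ru, "functional", tm) / pick(ru, "dysfunctional", tm),
                 pick(rd, "functional", tm), tolerance = 1e-6)
    # and the reciprocal relation for the unworried-vs-dysfunctional contrast
    expect_equal(1 / pick(ru, "dysfunctional", tm), pick(rd, "unworried", tm),
                 tolerance = 1e-6)
  }
})

test_that("negative binomial and Poisson agree when the outcome is equidispersed", {
  set.seed(33)
  d <- data.frame(x = rnorm(2000))
  d$y <- rpois(2000, exp(1 + 0.3 * d$x))  # theta -> infinity limit
  nb <- suppressWarnings(fit_model(model_spec("negative_binomial", "y", "x"), d))
  po <- fit_model(model_spec("poisson", "y", "x"), d)
  expect_equal(log(nb$estimate), po$estimate, tolerance = 1e-4, ignore_attr = TRUE)
  # poisson/linear report raw coefficients, not exponentiated
  expect_true(any(po$estimate < 0) || all(abs(po$estimate) < 5))
})

test_that("categorical reference levels are honoured", {
  d <- model_data(n = 700L, seed = 16L)
  res <- fit_model(model_spec("linear", "emotion_score",
                              c("age_band", "gender"),
                              reference_levels = list(age_band = "45-64", gender = "female")),
                   d)
  expect_false(any(grepl("45-64", res$term)))
  expect_true(any(grepl("male", res$term)))
})

test_that("degenerate designs are explicit errors", {
  d <- model_data(n = 300L, seed = 17L)
  d$dup <- d$impact_score
  expect_error(fit_model(model_spec("linear", "emotion_score",
                                    c("impact_score", "dup")), d),
               "aliased")
  expect_error(fit_model(model_spec("linear", "emotion_score", "impact_score"),
                         d[0, ]), "complete cases")
  expect_error(fit_model(model_spec("linear", "emotion_score", "not_a_column"), d),
               "missing from data")
  expect_error(fit_model(model_spec("multinomial_logit", "worry_group", "had_covid"),
                         d), "reference_outcome")
})

test_that("significance stars follow the strict table legend", {
  expect_equal(significance_stars(c(0.004, 0.05, 0.049, 0.0009, 0.2, NA)),
               c("**", "", "*", "***", "", ""))
})

test_that("model report stacks results and survives an empty list", {
  expect_equal(nrow(model_report(list())), 0)
  d <- model_data(n = 400L, seed = 18L)
  r1 <- fit_model(model_spec("linear", "emotion_score", "impact_score"), d)
  rep <- model_report(list(lin = r1))
  expect_equal(unique(rep$model), "lin")
  expect_true(all(c("estimate", "stars") %in% names(rep)))
})
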