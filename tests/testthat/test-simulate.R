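test_that("generation is deterministic given a seed and sensitive to it", {
  cfg <- generator_config(n_wave2 = 150L, seed = 4L)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$wave2, b$wave2)
  expect_identical(a$wave3, b$wave3)
  c2 <- generate_panel(generator_config(n_wave2 = 150L, seed = 5L))
  expect_false(identical(a$wave2, c2$wave2))
})

test_that("n = 0 yields empty, schema-complete tables and parameters in truth", {
  p <- generate_panel(generator_config(n_wave2 = 0L, seed = 1L))
  expect_equal(nrow(p$wave2), 0)
  expect_equal(nrow(p$wave3), 0)
  expect_true(all(default_codebook()$item %in% names(p$wave2)))
  expect_s3_class(p$truth$config, "generator_config")
})

test_that("the classifier recovers the latent group exactly (label fidelity)", {
  p <- generate_panel(generator_config(n_wave2 = 2000L, seed = 6L))
  expect_equal(as.character(classify_full(p$wave2)$worry_group), p$truth$group_wave2)
  obs3 <- !is.na(p$truth$group_wave3)
  expect_equal(as.character(classify_full(p$wave3)$worry_group),
               p$truth$group_wave3[obs3])
})

test_that("generated tables validate cleanly against the default codebook", {
  p <- generate_panel(generator_config(n_wave2 = 200L, seed = 8L))
  revalidated <- read_wave(as.data.frame(p$wave2), wave = 2)
  expect_equal(sum(validation_report(revalidated)$n_invalid), 0)
})

test_that("adversity indicator rates match their configured marginals at n=10,000", {
  cfg <- generator_config(n_wave2 = 10000L, seed = 9L)
  p <- generate_panel(cfg)
  for (it in names(cfg$experience_rates)) {
    rate <- cfg$experience_rates[[it]]
    got <- mean(p$wave2[[it]] == "yes")
    se <- sqrt(rate * (1 - rate) / 10000)
    expect_lt(abs(got - rate), 3 * se + 1e-9)
  }
})

test_that("attrition is near the configured retention rate", {
  cfg <- generator_config(n_wave2 = 5000L, seed = 10L)
  p <- generate_panel(cfg)
  se <- sqrt(cfg$wave3_retention * (1 - cfg$wave3_retention) / 5000)
  expect_lt(abs(nrow(p$wave3) / 5000 - cfg$wave3_retention), 3 * se)
  expect_true(all(p$wave3$respondent_id %in% p$wave2$respondent_id))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(transition_kernel = matrix(0.5, 3, 3)), "summing to 1")
  expect_error(generator_config(group_proportions = c(0.5, 0.4, 0.3)), "sum to 1")
  expect_error(generator_config(had_covid_rate = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(n_wave2 = -5L), "nonnegative")
})

test_that("risk perception orders the groups as intended", {
  p <- generate_panel(generator_config(n_wave2 = 8000L, seed = 13L))
  r <- recode_risk_perception(p$wave2)
  g <- p$truth$group_wave2
  mean_by <- function(v) tapply(v, g, mean)[worry_groups()]
  lik <- mean_by(r$likelihood); ctl <- mean_by(r$control); sev <- mean_by(r$severity)
  # dysfunctional highest likelihood/severity, lowest control
  expect_true(lik["unworried"] < lik["functional"] &
                lik["functional"] < lik["dysfunctional"])
  expect_true(ctl["unworried"] > ctl["functional"] &
                ctl["functional"] > ctl["dysfunctional"])
  expect_true(sev["dysfunctional"] > sev["unworried"])
})

test_that("the intercept calibration solves the marginal-share equations", {
  cfg <- generator_config()
  b <- worrytype:::calibrate_group_intercepts(cfg)
  # recompute the implied marginal shares by enumerating the covariate cells
  s_dist <- worrytype:::impact_score_distribution(cfg$experience_rates)
  cells <- expand.grid(h = 0:1, s = 0:8)
  cell_p <- ifelse(cells$h == 1, cfg$had_covid_rate, 1 - cfg$had_covid_rate) *
    s_dist[cells$s + 1]
  eta_f <- b["functional"] + cells$h * log(cfg$had_covid_rrr["functional"]) +
    cells$s * log(cfg$impact_rrr["functional"])
  eta_d <- b["dysfunctional"] + cells$h * log(cfg$had_covid_rrr["dysfunctional"]) +
    cells$s * log(cfg$impact_rrr["dysfunctional"])
  den <- 1 + exp(eta_f) + exp(eta_d)
  shares <- c(sum(cell_p / den), sum(cell_p * exp(eta_f) / den),
              sum(cell_p * exp(eta_d) / den))
  expect_equal(shares, as.numeric(cfg$group_proportions), tolerance = 1e-10)
  # the eight-indicator count distribution is a proper distribution
  expect_equal(sum(s_dist), 1, tolerance = 1e-12)
  expect_equal(length(s_dist), 9L)
})

test_that("the printed-cross-tab fixture has the documented cell structure", {
  fx <- fixture_from_crosstabs()
  expect_equal(nrow(fx), 1091L)
  expect_equal(sum(fx$worried == "no"), 401L)
  worried <- fx[fx$worried == "yes", ]
  expect_equal(sum(worried$takes_precautions == "no"), 34L)
  expect_equal(sum(worried$takes_precautions == "yes" & is.na(worried$feel_safer)), 10L)
  expect_equal(sum(validation_report(fx)$n_invalid), 0)
  expect_identical(fixture_from_crosstabs(), fx)  # fully deterministic
})
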