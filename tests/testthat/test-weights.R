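targets_2x2 <- margin_targets(gender = c(male = 0.5, female = 0.5),
                              age_band = c(young = 1))

test_that("cell-mode weights reproduce the closed-form ratios on a 2x2", {
  # 60 young males, 40 young females; 50/50 gender targets
  d <- data.frame(respondent_id = sprintf("r%03d", 1:100),
                  gender = rep(c("male", "female"), c(60, 40)),
                  age_band = "young")
  w <- compute_weights(d, targets_2x2, mode = "cell")
  expect_equal(unique(w$weight[d$gender == "male"]), 5 / 6)
  expect_equal(unique(w$weight[d$gender == "female"]), 5 / 4)
  expect_equal(sum(w$weight), 100)  # sum-preserving default total
})

test_that("sample margins already on target give constant weights", {
  d <- data.frame(respondent_id = as.character(1:40),
                  gender = rep(c("male", "female"), 20),
                  age_band = rep(c("young", "old"), each = 20))
  t <- margin_targets(gender = c(male = 0.5, female = 0.5),
                      age_band = c(young = 0.5, old = 0.5))
  for (mode in c("cell", "raking"))
    expect_equal(compute_weights(d, t, mode = mode)$weight, rep(1, 40))
})

test_that("post-weighting margins match targets within 1e-6 in both modes", {
  p <- generate_panel(generator_config(n_wave2 = 400L, seed = 5L))
  d <- as.data.frame(p$wave2)
  t <- margin_targets(gender = c(male = 0.48, female = 0.52),
                      age_band = c("16-24" = 0.14, "25-44" = 0.42,
                                   "45-64" = 0.31, "65+" = 0.13))
  for (mode in c("cell", "raking")) {
    w <- compute_weights(d, t, mode = mode)$weight
    expect_true(all(w > 0))
    got_g <- tapply(w, d$gender, sum) / sum(w)
    got_a <- tapply(w, d$age_band, sum) / sum(w)
    expect_equal(as.numeric(got_g[names(t$gender)]), as.numeric(t$gender),
                 tolerance = 1e-6)
    expect_equal(as.numeric(got_a[names(t$age_band)]), as.numeric(t$age_band),
                 tolerance = 1e-6)
  }
})

test_that("raking reproduces cell mode when the joint targets are consistent", {
  d <- data.frame(respondent_id = as.character(1:100),
                  gender = rep(c("male", "female"), c(60, 40)),
                  age_band = rep(c("young", "old"), 50))
  t <- margin_targets(gender = c(male = 0.5, female = 0.5),
                      age_band = c(young = 0.5, old = 0.5))
  w_cell <- compute_weights(d, t, mode = "cell")$weight
  w_rake <- compute_weights(d, t, mode = "raking")$weight
  expect_equal(w_rake, w_cell, tolerance = 1e-8)
})

test_that("weighted counts: unit weights, rescale invariance, arithmetic", {
  d <- data.frame(respondent_id = as.character(1:4),
                  g = c("A", "A", "B", "B"))
  wc <- weighted_counts(d, rep(1, 4), by = "g")
  expect_equal(wc$weighted_n, wc$n)
  # doubling all weights leaves percentages unchanged
  w <- c(2, 2, 0.5, 0.5)
  expect_equal(weighted_counts(d, 2 * w, by = "g")$weighted_pct,
               weighted_counts(d, w, by = "g")$weighted_pct)
  wc <- weighted_counts(d[c(1, 3), ], c(2, 0.5), by = "g")
  expect_equal(wc$weighted_pct, c(80, 20))
})

test_that("degenerate weighting inputs are hard errors", {
  d <- data.frame(respondent_id = as.character(1:4),
                  gender = "male", age_band = "young")
  expect_error(compute_weights(d, targets_2x2, mode = "cell"),
               "empty sample cells")
  expect_error(margin_targets(gender = c(male = 0.7, female = 0.4),
                              age_band = c(young = 1)), "sum to 1")
  expect_error(margin_targets(gender = c(male = -0.1, female = 1.1),
                              age_band = c(young = 1)), "nonnegative")
  d$gender[2] <- NA
  expect_error(compute_weights(d, targets_2x2), "nonmissing")
})
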