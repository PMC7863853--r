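test_that("impact score counts the eight adversity indicators only", {
  w <- small_wave_df(3)
  for (it in worrytype:::experience_items()) w[[it]] <- "no"
  expect_equal(covid_impact_score(w)$impact_score, c(0L, 0L, 0L))
  w$exp_self_job_loss[2] <- "yes"; w$exp_lost_accommodation[2] <- "yes"
  for (it in worrytype:::experience_items()) w[[it]][3] <- "yes"
  w$had_covid <- "yes"  # infection history must not enter the index
  sc <- covid_impact_score(w)
  expect_equal(sc$impact_score, c(0L, 2L, 8L))
  # missing indicators count 0 but are flagged
  w$exp_close_died[1] <- NA
  sc <- covid_impact_score(w)
  expect_equal(sc$impact_score[1], 0L)
  expect_equal(sc$n_missing_components, c(1L, 0L, 0L))
})

test_that("emotion binary recode keys bad outcomes as yes in both directions", {
  expect_equal(recode_emotion_binary("not at all", "emo_anxiety"), "no")
  expect_equal(recode_emotion_binary("a little", "emo_anger"), "yes")
  expect_equal(recode_emotion_binary("not at all", "emo_happiness"), "yes")
  expect_equal(recode_emotion_binary("very much", "emo_satisfied"), "no")
  expect_true(is.na(recode_emotion_binary(NA, "emo_anxiety")))
  expect_error(recode_emotion_binary("a little", "anxiety"), "unknown emotion item")
})

test_that("emotion score is the reverse-keyed sum, bounded in [6, 30]", {
  w <- small_wave_df(3)
  neg <- setdiff(worrytype:::emotion_items(), worrytype:::emotion_positive_items())
  # best possible: negative emotions at floor, positive at ceiling
  for (it in neg) w[[it]] <- "not at all"
  for (it in worrytype:::emotion_positive_items()) w[[it]] <- "very much"
  expect_equal(emotion_score(w), c(6L, 6L, 6L))
  # worst possible
  for (it in neg) w[[it]] <- "very much"
  for (it in worrytype:::emotion_positive_items()) w[[it]] <- "not at all"
  expect_equal(emotion_score(w), c(30L, 30L, 30L))
  # single item moved: anxiety at the third level adds 2 over the floor
  for (it in neg) w[[it]] <- "not at all"
  for (it in worrytype:::emotion_positive_items()) w[[it]] <- "very much"
  w$emo_anxiety[1] <- "moderately"
  expect_equal(emotion_score(w), c(8L, 6L, 6L))
  # missing item -> missing score, never imputed
  w$emo_anger[2] <- NA
  expect_true(is.na(emotion_score(w)[2]))
})

test_that("reverse-keying is an involution on the raw items", {
  raw <- sample(lik5_levels, 50, TRUE)
  v <- match(raw, lik5_levels)
  expect_equal(lik5_levels[6L - (6L - v)], raw)
})

test_that("random matrices: alpha agrees with the covariance-matrix oracle to 1e-12", {
  # independent oracle: alpha from the covariance matrix, (k/(k-1)) *
  # (1 - tr(S)/sum(S)) -- algebraically distinct route from the item/total
  # variance formula used by the implementation
  alpha_cov_oracle <- function(m) {
    S <- stats::cov(m)
    k <- ncol(m)
    (k / (k - 1)) * (1 - sum(diag(S)) / sum(S))
  }
  set.seed(77)
  for (i in 1:20) {
    m <- matrix(sample(1:5, 60, TRUE), 10, 6)
    if (stats::var(rowSums(m)) == 0) next
    expect_equal(cronbach_alpha(m), alpha_cov_oracle(m), tolerance = 1e-12)
  }
})

test_that("alpha edge cases: identical columns, independence, degenerate input", {
  set.seed(8)
  x <- sample(1:5, 40, TRUE)
  expect_equal(cronbach_alpha(cbind(x, x, x, x, x, x)), 1.0)
  # six mutually independent columns at large n: alpha near 0
  m <- matrix(stats::runif(10000 * 6), ncol = 6)
  expect_lt(abs(cronbach_alpha(m)), 0.05)
  expect_error(cronbach_alpha(matrix(1, 5, 6)), "zero variance")
  expect_error(cronbach_alpha(matrix(1:6, 1, 6)), "at least 2")
})

test_that("re-engagement score is wave-3 minus wave-2 with the stated sign convention", {
  w2 <- small_wave_df(3)
  w3 <- small_wave_df(3)
  ci <- worrytype:::compliance_items()
  w2[ci] <- list(c(1L, 3L, 2L), c(1L, 2L, 2L), c(1L, 2L, 3L))
  w3[ci] <- w2[ci]
  p <- list(wave2 = w2, wave3 = w3)
  expect_equal(reengagement_score(p)$value, c(0, 0, 0))  # no change
  w3[ci] <- list(c(3L, 1L, 2L), c(2L, 1L, 2L), c(2L, 1L, 3L))
  r <- reengagement_score(p <- list(wave2 = w2, wave3 = w3))
  # respondent 1 re-engaged (+4); respondent 2 was more engaged in wave 2 (-4)
  expect_equal(r$value, c(4, -4, 0))
  expect_equal(r$w3_total - r$w2_total, r$value)
  expect_equal(r$d_comp_socialised, c(2, -2, 0))
  # any missing activity item voids the score
  w3$comp_travel_leisure[1] <- NA
  expect_true(is.na(reengagement_score(list(wave2 = w2, wave3 = w3))$value[1]))
})

test_that("risk-perception recode is the codebook-ordered integer coding", {
  w <- small_wave_df(2)
  w$risk_likelihood <- c("not at all", "very much")
  w$risk_control <- c("not at all", "a little")
  w$risk_severity <- c("not at all", "moderately")
  r <- recode_risk_perception(w)
  expect_equal(unlist(r[1, ]), c(likelihood = 1L, control = 1L, severity = 1L))
  expect_equal(r$likelihood[2], 5L)
  # monotone relabelling leaves the rank order unchanged
  expect_equal(order(r$severity), order(match(w$risk_severity, lik5_levels)))
})

test_that("scores are per-record: permuting respondents permutes scores", {
  p <- generate_panel(generator_config(n_wave2 = 60L, seed = 12L))
  w <- as.data.frame(p$wave2)
  perm <- sample(nrow(w))
  expect_equal(covid_impact_score(w[perm, ])$impact_score,
               covid_impact_score(w)$impact_score[perm])
  expect_equal(emotion_score(w[perm, ]), emotion_score(w)[perm])
})
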