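#' Configuration of the synthetic two-wave panel generator
#'
#' All distributional parameters of the synthetic panel. The defaults encode
#' the study conditions the analyses assume: wave sizes of a ten-city UK
#' online panel (1100 then 1019), unweighted group shares 401/203/487 out of
#' 1091 classified, a wave-to-wave transition kernel with diagonal 0.71,
#' adversity indicator rates of 14/10/6/0.4/5/2/3/3 percent, infection-
#' history and adversity effects on group membership expressed as
#' relative-risk ratios (2.439 and 1.012 for had-COVID, 0.979 and 1.465 per
#' adversity point, functional and dysfunctional vs unworried), and an
#' emotion-score model with baseline mean 14.312, group multipliers
#' 0.913/1.164, and negative-binomial dispersion theta 151.136.
#'
#' Group membership is generated structurally: infection history and the
#' adversity indicators are drawn first, the wave-2 group follows a
#' multinomial logit in those covariates with the configured relative-risk
#' ratios (intercepts calibrated so the marginal group shares hit
#' `group_proportions`), and the wave-3 group follows the transition kernel.
#' Answer items are then filled in *within the defining cell of each group*,
#' so the full classifier recovers the latent group exactly.
#'
#' @param n_wave2 number of wave-2 respondents.
#' @param wave3_retention probability a wave-2 respondent is retained at
#'   wave 3 (missing completely at random).
#' @param group_proportions length-3 probabilities (unworried, functional,
#'   dysfunctional), summing to 1.
#' @param transition_kernel 3x3 row-stochastic matrix of wave-2 to wave-3
#'   group transition probabilities (rows/cols in the fixed group order).
#' @param had_covid_rate marginal probability of reporting having (or
#'   suspecting having) had COVID-19.
#' @param had_covid_rrr,impact_rrr named length-2 vectors
#'   (`functional`, `dysfunctional`): relative-risk ratios vs unworried per
#'   had-COVID and per adversity-score point.
#' @param experience_rates named length-8 marginal probabilities of the
#'   adversity indicators.
#' @param emotion_baseline_mean,emotion_group_multipliers,emotion_theta
#'   emotion-score model: unworried mean, multiplicative group effects
#'   (unworried, functional, dysfunctional), and negative-binomial dispersion
#'   of the score.
#' @param dysfunctional_cell_probs length-4 probabilities over the defining
#'   cells of the dysfunctional group (precautions-and-safer-but-QoL-affected,
#'   no precautions, precautions-not-safer, feel-safer unanswered).
#' @param no_precaution_qol_low_share among no-precaution dysfunctionals,
#'   share whose quality-of-life answers are both in the low band.
#' @param risk_means 3x3 matrix of latent means for the risk-perception triad
#'   (rows = groups; columns = likelihood, control, severity) on the 1-5
#'   scale: dysfunctionals see the highest likelihood/severity and the
#'   lowest control.
#' @param compliance_prob per-wave success probability of the binomial(4)
#'   compliance-frequency items (wave 2, wave 3); the wave-3 value is higher
#'   because restrictions had eased.
#' @param seed integer RNG seed; every call with the same config is
#'   byte-identical.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_wave2 = 1100L,
                             wave3_retention = 1019 / 1100,
                             group_proportions = c(unworried = 401, functional = 203,
                                                   dysfunctional = 487) / 1091,
                             transition_kernel = default_transition_kernel(0.71),
                             had_covid_rate = 171 / 1100,
                             had_covid_rrr = c(functional = 2.439, dysfunctional = 1.012),
                             impact_rrr = c(functional = 0.979, dysfunctional = 1.465),
                             experience_rates = c(exp_self_job_loss = 0.14,
                                                  exp_household_job_loss = 0.10,
                                                  exp_unable_pay_bills = 0.06,
                                                  exp_unable_access_food = 0.004,
                                                  exp_unable_access_medication = 0.05,
                                                  exp_lost_accommodation = 0.02,
                                                  exp_close_hospitalised = 0.03,
                                                  exp_close_died = 0.03),
                             emotion_baseline_mean = 14.312,
                             emotion_group_multipliers = c(unworried = 1,
                                                           functional = 0.913,
                                                           dysfunctional = 1.164),
                             emotion_theta = 151.136,
                             dysfunctional_cell_probs = c(precautions_safer_affected = 438,
                                                          no_precautions = 34,
                                                          precautions_not_safer = 5,
                                                          safer_missing = 10) / 487,
                             no_precaution_qol_low_share = 3 / 34,
                             risk_means = matrix(c(2.2, 3.4, 2.5,
                                                   2.7, 3.1, 2.9,
                                                   3.3, 2.7, 3.4),
                                                 nrow = 3, byrow = TRUE,
                                                 dimnames = list(worry_groups(),
                                                                 c("likelihood", "control",
                                                                   "severity"))),
                             compliance_prob = c(wave2 = 0.22, wave3 = 0.38),
                             seed = 1L) {
  cfg <- list(n_wave2 = as.integer(n_wave2), wave3_retention = wave3_retention,
              group_proportions = group_proportions,
              transition_kernel = transition_kernel,
              had_covid_rate = had_covid_rate,
              had_covid_rrr = had_covid_rrr, impact_rrr = impact_rrr,
              experience_rates = experience_rates,
              emotion_baseline_mean = emotion_baseline_mean,
              emotion_group_multipliers = emotion_group_multipliers,
              emotion_theta = emotion_theta,
              dysfunctional_cell_probs = dysfunctional_cell_probs,
              no_precaution_qol_low_share = no_precaution_qol_low_share,
              risk_means = risk_means,
              compliance_prob = compliance_prob,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param diagonal staying probability shared by all three groups; movers
#'   split equally between the two other groups.
#' @export
default_transition_kernel <- function(diagonal = 0.71) {
  off <- (1 - diagonal) / 2
  k <- matrix(off, 3, 3, dimnames = list(worry_groups(), worry_groups()))
  diag(k) <- diagonal
  k
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$wave3_retention, cfg$had_covid_rate, cfg$experience_rates,
             cfg$group_proportions, cfg$dysfunctional_cell_probs,
             cfg$compliance_prob, as.vector(cfg$transition_kernel),
             cfg$no_precaution_qol_low_share)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$group_proportions) - 1) > 1e-8)
    stop("group_proportions must sum to 1")
  if (length(cfg$group_proportions) != 3L || length(cfg$experience_rates) != 8L)
    stop("group_proportions must have length 3 and experience_rates length 8")
  if (!all(dim(cfg$transition_kernel) == c(3L, 3L)) ||
      any(abs(rowSums(cfg$transition_kernel) - 1) > 1e-8))
    stop("transition_kernel must be 3x3 with rows summing to 1")
  if (abs(sum(cfg$dysfunctional_cell_probs) - 1) > 1e-8)
    stop("dysfunctional_cell_probs must sum to 1")
  if (cfg$n_wave2 < 0L) stop("n_wave2 must be nonnegative")
  invisible(cfg)
}

# Distribution of the adversity count: Poisson-binomial over the eight
# independent indicators, by direct convolution.
impact_score_distribution <- function(rates) {
  p <- c(1)
  for (r in rates) p <- c(p * (1 - r), 0) + c(0, p * r)
  p
}

# Solve the multinomial-logit intercepts so that the marginal group shares
# equal the targets when covariate effects are as configured. Fixed-point
# iteration on the log-share mismatch; deterministic given the config.
calibrate_group_intercepts <- function(cfg) {
  s_dist <- impact_score_distribution(cfg$experience_rates)
  cells <- expand.grid(h = 0:1, s = 0:8)
  cell_p <- ifelse(cells$h == 1, cfg$had_covid_rate, 1 - cfg$had_covid_rate) *
    s_dist[cells$s + 1]
  lh <- log(cfg$had_covid_rrr)
  ls <- log(cfg$impact_rrr)
  target <- cfg$group_proportions
  b <- log(target[2:3] / target[1])  # start from the no-covariate solution
  for (iter in 1:200) {
    eta_f <- b[1] + cells$h * lh["functional"] + cells$s * ls["functional"]
    eta_d <- b[2] + cells$h * lh["dysfunctional"] + cells$s * ls["dysfunctional"]
    den <- 1 + exp(eta_f) + exp(eta_d)
    cur <- c(sum(cell_p / den), sum(cell_p * exp(eta_f) / den),
             sum(cell_p * exp(eta_d) / den))
    step <- log(target[2:3] / cur[2:3]) - log(target[1] / cur[1])
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  names(b) <- c("functional", "dysfunctional")
  b
}

clamp_likert <- function(x, levels) {
  idx <- pmin(pmax(round(x), 1L), length(levels))
  levels[idx]
}

# Balanced allocation of the emotion score onto six 1-5 items: every item
# gets the integer part of (score - 6)/6 extra points and the remainder goes
# to a uniformly random subset, so items differ by at most one point. A
# sum-preserving random point transfer then roughens the profile: with
# probability `transfer_prob` one point moves from a random item to another
# (where feasible). The transfer rate is calibrated so six items at the
# study's sample size show internal consistency near alpha = 0.88; without
# it the balanced profiles are too consistent (alpha ~ 0.94).
allocate_emotion_items <- function(score, n_items = 6L, transfer_prob = 0.5) {
  n <- length(score)
  extra <- score - n_items
  q <- extra %/% n_items
  r <- extra %% n_items
  u <- matrix(stats::runif(n * n_items), n, n_items)
  # within-row ranks without an R-level loop: offset rows into disjoint bands
  v <- as.vector(t(u)) + rep(seq_len(n) - 1, each = n_items)
  within <- rank(v) - (rep(seq_len(n) - 1, each = n_items)) * n_items
  within <- matrix(within, n, n_items, byrow = TRUE)
  items <- matrix(1L + q, n, n_items) + (within <= r)
  storage.mode(items) <- "integer"
  if (n > 0 && transfer_prob > 0) {
    do_it <- stats::runif(n) < transfer_prob
    donor <- sample.int(n_items, n, TRUE)
    recip <- sample.int(n_items, n, TRUE)
    di <- cbind(seq_len(n), donor)
    ri <- cbind(seq_len(n), recip)
    ok <- do_it & donor != recip & items[di] > 1L & items[ri] < 5L
    items[di[ok, , drop = FALSE]] <- items[di[ok, , drop = FALSE]] - 1L
    items[ri[ok, , drop = FALSE]] <- items[ri[ok, , drop = FALSE]] + 1L
  }
  items
}

# Draw emotion scores: a shifted negative-binomial count 6 + NB(mu - 6,
# theta*), where theta* is chosen per group so the total-score variance
# equals that of NB(mu, emotion_theta). Clipped to the feasible [6, 30].
draw_emotion_scores <- function(group, cfg) {
  mult <- cfg$emotion_group_multipliers[as.character(group)]
  mu <- cfg$emotion_baseline_mean * mult
  mu_star <- pmax(mu - 6, 0.1)
  var_target <- mu + mu^2 / cfg$emotion_theta
  excess <- var_target - mu_star
  s <- integer(length(mu))
  nb <- excess > 1e-8
  if (any(nb)) {
    size <- mu_star[nb]^2 / excess[nb]
    s[nb] <- stats::rnbinom(sum(nb), mu = mu_star[nb], size = size)
  }
  if (any(!nb)) s[!nb] <- stats::rpois(sum(!nb), mu_star[!nb])
  6L + pmin(s, 24L)
}

lik5 <- function() c("not at all", "a little", "moderately", "quite a bit", "very much")

# Fill the worry / precaution / quality-of-life block so that classify_full
# recovers `group` exactly: answers are drawn within each group's defining
# cell of the precaution x quality-of-life cross-tabulation.
fill_worry_block <- function(group, cfg) {
  n <- length(group)
  lv <- lik5()
  low <- lv[1:2]; high <- lv[3:5]; pos <- lv[3:5]
  samp <- function(k, levels, prob) if (k > 0) sample(levels, k, TRUE, prob) else character(0)

  out <- data.frame(worried = rep(NA_character_, n), worry_frequency = NA_character_,
                    worry_intensity = NA_character_, takes_precautions = NA_character_,
                    feel_safer = NA_character_, qol_worry = NA_character_,
                    qol_precautions = NA_character_)
  u <- group == "unworried"
  out$worried[u] <- "no"
  out$takes_precautions[u] <- samp(sum(u), c("no", "yes"), c(0.15, 0.85))
  has_prec_u <- u & out$takes_precautions == "yes"
  out$feel_safer[has_prec_u] <- samp(sum(has_prec_u), lv, c(0.05, 0.12, 0.30, 0.33, 0.20))
  out$qol_worry[u] <- "not at all"
  out$qol_precautions[u] <- samp(sum(u), lv, c(0.45, 0.25, 0.15, 0.10, 0.05))

  w <- !u
  out$worried[w] <- "yes"
  out$worry_frequency[w] <- samp(sum(w), c("once or twice", "three to ten times",
                                           "more than ten times"), c(0.35, 0.44, 0.21))
  out$worry_intensity[w] <- samp(sum(w), c("not very worried", "a bit worried",
                                           "fairly worried", "very worried"),
                                 c(0.12, 0.30, 0.37, 0.21))

  f <- group == "functional"
  out$takes_precautions[f] <- "yes"
  out$feel_safer[f] <- samp(sum(f), pos, c(0.35, 0.40, 0.25))
  out$qol_worry[f] <- samp(sum(f), low, c(0.55, 0.45))
  out$qol_precautions[f] <- samp(sum(f), low, c(0.55, 0.45))

  d <- group == "dysfunctional"
  cell <- samp(sum(d), names(cfg$dysfunctional_cell_probs), cfg$dysfunctional_cell_probs)
  idx <- which(d)
  draw_affected_pair <- function(k) {
    # quadrant mix among the quality-of-life-affected: both / worry-only /
    # precautions-only
    quad <- samp(k, c("both", "worry", "prec"), c(236, 82, 122) / 440)
    qw <- ifelse(quad %in% c("both", "worry"),
                 samp(k, high, c(0.5, 0.3, 0.2)), samp(k, low, c(0.6, 0.4)))
    qp <- ifelse(quad %in% c("both", "prec"),
                 samp(k, high, c(0.5, 0.3, 0.2)), samp(k, low, c(0.6, 0.4)))
    list(qw = qw, qp = qp)
  }
  i1 <- idx[cell == "precautions_safer_affected"]
  out$takes_precautions[i1] <- "yes"
  out$feel_safer[i1] <- samp(length(i1), pos, c(0.35, 0.40, 0.25))
  qq <- draw_affected_pair(length(i1))
  out$qol_worry[i1] <- qq$qw; out$qol_precautions[i1] <- qq$qp

  i2 <- idx[cell == "no_precautions"]
  out$takes_precautions[i2] <- "no"
  lowboth <- stats::runif(length(i2)) < cfg$no_precaution_qol_low_share
  out$qol_worry[i2] <- ifelse(lowboth, samp(length(i2), low, c(0.6, 0.4)),
                              samp(length(i2), high, c(0.5, 0.3, 0.2)))
  out$qol_precautions[i2] <- samp(length(i2), low, c(0.7, 0.3))

  i3 <- idx[cell == "precautions_not_safer"]
  out$takes_precautions[i3] <- "yes"
  out$feel_safer[i3] <- samp(length(i3), lv[1:2], c(0.5, 0.5))
  qq <- draw_affected_pair(length(i3))
  out$qol_worry[i3] <- qq$qw; out$qol_precautions[i3] <- qq$qp

  i4 <- idx[cell == "safer_missing"]
  out$takes_precautions[i4] <- "yes"     # feel_safer left missing
  qq <- draw_affected_pair(length(i4))
  out$qol_worry[i4] <- qq$qw; out$qol_precautions[i4] <- qq$qp

  out
}

# Wave-varying blocks other than the worry block.
fill_outcome_blocks <- function(group, cfg, wave) {
  n <- length(group)
  lv <- lik5()
  out <- data.frame(row.names = seq_len(n))

  escore <- draw_emotion_scores(group, cfg)
  items <- allocate_emotion_items(escore)
  colnames(items) <- emotion_items()
  for (it in emotion_items()) {
    v <- items[, it]
    if (it %in% emotion_positive_items()) v <- 6L - v  # store on the asked scale
    out[[it]] <- lv[v]
  }

  p <- cfg$compliance_prob[[paste0("wave", wave)]]
  for (it in compliance_items()) out[[it]] <- stats::rbinom(n, 4, p)

  rm <- cfg$risk_means[as.character(group), , drop = FALSE]
  out$risk_likelihood <- clamp_likert(stats::rnorm(n, rm[, "likelihood"], 1), lv)
  out$risk_control <- clamp_likert(stats::rnorm(n, rm[, "control"], 1), lv)
  out$risk_severity <- clamp_likert(stats::rnorm(n, rm[, "severity"], 1), lv)

  out$knowledge <- clamp_likert(stats::rnorm(n, 3.5, 0.9), lv)
  for (block in covariate_blocks()) {
    fac <- stats::rnorm(n)
    for (it in block)
      out[[it]] <- clamp_likert(3 + 0.9 * fac + stats::rnorm(n, 0, 0.7), lv)
  }
  out
}

#' Generate a synthetic two-wave panel
#'
#' Draws a complete two-wave unit-record panel from a [generator_config()]:
#' latent worry groups first (wave 2 from the calibrated covariate model,
#' wave 3 through the transition kernel, with missing-completely-at-random
#' attrition), then every questionnaire item conditional on the group. By
#' construction [classify_full()] recovers the latent groups exactly.
#'
#' @param config a [generator_config()].
#' @return A list with `wave2` and `wave3` (validated wave tables) and
#'   `truth`: the latent wave-2/wave-3 groups per respondent, the calibrated
#'   model intercepts, and the config.
#' @export
generate_panel <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_wave2
  cb <- default_codebook()
  intercepts <- calibrate_group_intercepts(config)

  if (n == 0L) {
    empty <- utils::read.csv(text = paste(c("respondent_id", cb$item), collapse = ","),
                             colClasses = "character")
    w2 <- validate_wave(empty, cb, 2L)
    w3 <- validate_wave(empty, cb, 3L)
    return(list(wave2 = w2, wave3 = w3,
                truth = list(config = config, intercepts = intercepts,
                             group_wave2 = character(0), group_wave3 = character(0))))
  }

  id <- sprintf("r%05d", seq_len(n))
  demo <- data.frame(
    respondent_id = id,
    age_band = sample(c("16-24", "25-44", "45-64", "65+"), n, TRUE,
                      c(0.16, 0.44, 0.30, 0.10)),
    gender = sample(c("male", "female"), n, TRUE, c(0.49, 0.51)),
    ethnicity = sample(c("White", "BAME"), n, TRUE, c(0.80, 0.20)),
    keyworker = sample(c("no", "yes"), n, TRUE, c(0.67, 0.33)),
    city = sample(c("Birmingham", "Cardiff", "Edinburgh", "Glasgow", "Leeds",
                    "Liverpool", "London", "Manchester", "Newcastle", "Sheffield",
                    "none of these"), n, TRUE, c(rep(0.093, 10), 0.07)))

  had <- stats::rbinom(n, 1, config$had_covid_rate)
  suspected <- stats::rbinom(n, 1, 0.1)
  expm <- sapply(config$experience_rates, function(r) stats::rbinom(n, 1, r))
  expm <- matrix(expm, nrow = n, dimnames = list(NULL, names(config$experience_rates)))
  impact <- rowSums(expm)

  history <- data.frame(had_covid = c("no", "yes")[had + 1],
                        suspected_covid = c("no", "yes")[suspected + 1])
  history <- cbind(history, as.data.frame(apply(expm, 2, function(x) c("no", "yes")[x + 1])))

  # wave-2 latent group: multinomial logit in (had_covid, adversity count)
  eta_f <- intercepts["functional"] + had * log(config$had_covid_rrr["functional"]) +
    impact * log(config$impact_rrr["functional"])
  eta_d <- intercepts["dysfunctional"] + had * log(config$had_covid_rrr["dysfunctional"]) +
    impact * log(config$impact_rrr["dysfunctional"])
  den <- 1 + exp(eta_f) + exp(eta_d)
  u <- stats::runif(n)
  g2 <- ifelse(u < 1 / den, "unworried",
               ifelse(u < (1 + exp(eta_f)) / den, "functional", "dysfunctional"))

  # wave-3 latent group via the transition kernel; attrition is MCAR
  kern <- config$transition_kernel
  cum <- t(apply(kern, 1, cumsum))
  u3 <- stats::runif(n)
  row_i <- match(g2, worry_groups())
  g3 <- worry_groups()[1L + (u3 > cum[row_i, 1]) + (u3 > cum[row_i, 2])]
  retained <- stats::runif(n) < config$wave3_retention

  w2 <- cbind(demo, fill_worry_block(g2, config), history,
              fill_outcome_blocks(g2, config, wave = 2))
  w3 <- cbind(demo[retained, , drop = FALSE],
              fill_worry_block(g3[retained], config),
              history[retained, , drop = FALSE],
              fill_outcome_blocks(g3[retained], config, wave = 3))

  w2 <- validate_wave(w2, cb, 2L)
  w3 <- validate_wave(w3, cb, 3L)
  g3_obs <- ifelse(retained, g3, NA_character_)
  list(wave2 = w2, wave3 = w3,
       truth = list(config = config, intercepts = intercepts,
                    group_wave2 = g2, group_wave3 = g3_obs,
                    impact_score = impact, had_covid = had))
}

#' Deterministic wave-2 fixture from the published cross-tabulations
#'
#' Rebuilds a unit-record wave-2 table with exactly the published cell
#' counts of the worry / precaution / quality-of-life cross-tabulations:
#' 401 unworried; among the 690 worried, 34 took no precautions, 641 took
#' precautions and felt safer, 5 took precautions without feeling safer, and
#' 10 did not answer the feel-safer item; the 641 split 203 (quality of life
#' untouched by both worry and precautions — the functional cell) against
#' 438; 3 of the no-precaution respondents sit in the low-impact column and
#' the 10 feel-safer non-answerers in the affected column. Every other item
#' is filled deterministically with valid codebook levels, so the fixture is
#' a complete, validated wave table of 1091 records.
#'
#' @return A validated wave table (see [read_wave()]) with 1091 rows.
#' @export
fixture_from_crosstabs <- function() {
  lv <- lik5()
  low <- lv[1:2]; high <- lv[3:5]; pos <- lv[3:5]
  cyc <- function(pool, k, phase = 0L) pool[((seq_len(k) - 1L + phase) %% length(pool)) + 1L]

  blocks <- list(
    # 401 unworried: answers to the follow-ups are irrelevant to the label
    data.frame(worried = "no", takes_precautions = cyc(c("yes", "no"), 401),
               feel_safer = cyc(lv, 401), qol_worry = "not at all",
               qol_precautions = cyc(lv, 401, 2L)),
    # 203 functional: precautions, felt safer, quality of life untouched
    data.frame(worried = "yes", takes_precautions = "yes",
               feel_safer = cyc(pos, 203), qol_worry = cyc(low, 203),
               qol_precautions = cyc(low, 203, 1L)),
    # 438 precautions-and-safer with quality of life affected
    data.frame(worried = "yes", takes_precautions = "yes",
               feel_safer = cyc(pos, 438, 1L), qol_worry = cyc(c(high, low[1]), 438),
               qol_precautions = cyc(high, 438, 2L)),
    # 34 no precautions: 3 low-impact-both, 31 affected
    data.frame(worried = "yes", takes_precautions = "no",
               feel_safer = NA_character_,
               qol_worry = c(rep("not at all", 3), cyc(high, 31)),
               qol_precautions = c(rep("a little", 3), cyc(low, 31))),
    # 5 precautions but not feeling safer, quality of life affected
    data.frame(worried = "yes", takes_precautions = "yes",
               feel_safer = cyc(lv[1:2], 5), qol_worry = cyc(high, 5),
               qol_precautions = cyc(high, 5, 1L)),
    # 10 precautions but feel-safer unanswered, quality of life affected
    data.frame(worried = "yes", takes_precautions = "yes",
               feel_safer = NA_character_, qol_worry = cyc(high, 10),
               qol_precautions = cyc(high, 10, 1L))
  )
  worry <- do.call(rbind, blocks)
  n <- nrow(worry)

  dat <- cbind(data.frame(respondent_id = sprintf("f%04d", seq_len(n))), worry)
  dat$worry_frequency <- ifelse(dat$worried == "yes",
                                cyc(c("once or twice", "three to ten times",
                                      "more than ten times"), n), NA)
  dat$worry_intensity <- ifelse(dat$worried == "yes",
                                cyc(c("not very worried", "a bit worried",
                                      "fairly worried", "very worried"), n), NA)
  dat$had_covid <- cyc(c(rep("no", 5), "yes"), n)
  dat$suspected_covid <- cyc(c(rep("no", 9), "yes"), n)
  for (i in seq_along(experience_items()))
    dat[[experience_items()[i]]] <- cyc(c(rep("no", 7 + i), "yes"), n, i)
  for (i in seq_along(emotion_items()))
    dat[[emotion_items()[i]]] <- cyc(lv, n, i)
  for (i in seq_along(compliance_items()))
    dat[[compliance_items()[i]]] <- cyc(0:4, n, i)
  dat$risk_likelihood <- cyc(lv, n, 1L)
  dat$risk_control <- cyc(lv, n, 2L)
  dat$risk_severity <- cyc(lv, n, 3L)
  dat$knowledge <- cyc(lv, n, 4L)
  for (block in covariate_blocks())
    for (i in seq_along(block)) dat[[block[i]]] <- cyc(lv, n, i)
  dat$age_band <- cyc(c("16-24", "25-44", "45-64", "65+"), n)
  dat$gender <- cyc(c("male", "female"), n)
  dat$ethnicity <- cyc(c(rep("White", 4), "BAME"), n)
  dat$keyworker <- cyc(c("no", "no", "yes"), n)
  dat$city <- cyc(c("Birmingham", "Cardiff", "Edinburgh", "Glasgow", "Leeds",
                    "Liverpool", "London", "Manchester", "Newcastle", "Sheffield"), n)
  validate_wave(dat, default_codebook(), 2L)
}
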