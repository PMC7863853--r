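#!/usr/bin/env Rscript
# Stage 6: the four association model families.
#  - multinomial logit: worry-group membership from infection history and
#    adversity count (reference: unworried), and a wave-3 risk-perception
#    model with dysfunctional worry as the reference category;
#  - negative binomial: summative emotion score by worry group;
#  - Poisson: wave-3 non-compliance count with principal-component scores of
#    the attitudinal covariate blocks and an age x gender interaction;
#  - linear: re-engagement change score on both waves' component scores.

library(worrytype)

w2 <- read_wave("results/sim/wave2.csv", wave = 2)
w3 <- read_wave("results/sim/wave3.csv", wave = 3)
panel <- link_panel(w2, w3)

prep <- function(w) {
  d <- as.data.frame(w)
  d$impact_score <- covid_impact_score(d)$impact_score
  d$emotion_score <- emotion_score(d)
  d$worry_group <- droplevels(classify_full(d)$worry_group)
  # first-principal-component scores of each attitudinal block
  for (bl in names(worrytype:::covariate_blocks())) {
    items <- worrytype:::covariate_blocks()[[bl]]
    m <- sapply(items, function(it) match(d[[it]],
      c("not at all", "a little", "moderately", "quite a bit", "very much")))
    d[[paste0("pc_", bl)]] <- pca_block_score(m, bl)
  }
  risk <- recode_risk_perception(d)
  d$risk_likelihood_i <- risk$likelihood
  d$risk_control_i <- risk$control
  d$risk_severity_i <- risk$severity
  d$noncompliance <- rowSums(sapply(worrytype:::compliance_items(),
                                    function(it) as.numeric(d[[it]])))
  # combined age x gender cells, reported the way interaction rows are shown
  d$age_gender <- paste(d$age_band, d$gender)
  d
}
d2 <- prep(w2)
d3 <- prep(w3)

refs <- list(age_band = "16-24", city = "Birmingham", gender = "male",
             ethnicity = "BAME")

fits <- list()
fits$group_membership <- fit_model(model_spec(
  "multinomial_logit", "worry_group",
  c("had_covid", "impact_score", "age_band", "gender", "ethnicity",
    "keyworker", "city"),
  reference_outcome = "unworried", reference_levels = refs), d2)

fits$risk_perception <- fit_model(model_spec(
  "multinomial_logit", "worry_group",
  c("risk_likelihood_i", "risk_control_i", "risk_severity_i"),
  reference_outcome = "dysfunctional"), d3)

fits$emotion <- suppressWarnings(fit_model(model_spec(
  "negative_binomial", "emotion_score",
  c("worry_group", "had_covid", "impact_score", "age_band", "gender"),
  reference_levels = c(list(worry_group = "unworried"), refs["age_band"])), d2))

fits$noncompliance <- fit_model(model_spec(
  "poisson", "noncompliance",
  c("knowledge", "pc_deterrence", "pc_legal_legitimacy", "pc_police_legitimacy",
    "pc_social_norms", "pc_expressive_law", "worry_group", "age_gender", "city"),
  reference_levels = c(list(worry_group = "unworried", age_gender = "16-24 male"),
                       refs["city"])), d3)

reeng <- reengagement_score(panel)
dl <- merge(reeng[, c("respondent_id", "value")], d2, by = "respondent_id")
fits$reengagement <- fit_model(model_spec(
  "linear", "value",
  c("pc_deterrence", "pc_legal_legitimacy", "pc_police_legitimacy",
    "pc_social_norms", "pc_expressive_law", "worry_group"),
  reference_levels = list(worry_group = "unworried")), dl)

report <- model_report(fits)
write_outputs(list(model_tables = report), "results")

for (nm in names(fits)) {
  cat(sprintf("\n== %s (%s, n=%d, AIC=%.1f)\n", nm, attr(fits[[nm]], "family"),
              attr(fits[[nm]], "n"), attr(fits[[nm]], "aic")))
  r <- report[report$model == nm, ]
  key <- r[grepl("worry_group|had_covid|impact_score|risk_", r$term), ]
  if (nrow(key)) print(key[, c("outcome_level", "term", "estimate", "p_value", "stars")],
                       row.names = FALSE)
}
cat(sprintf("\nemotion model dispersion theta: %.1f\n", attr(fits$emotion, "theta")))
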