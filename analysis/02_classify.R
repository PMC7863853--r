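#!/usr/bin/env Rscript
# Stage 2: classify respondents into unworried / functional / dysfunctional
# worry. Runs on (a) the deterministic fixture rebuilt from the published
# wave-2 cross-tabulations — which reproduces the printed 401/203/487 split —
# and (b) wave 2 of the synthetic panel from stage 1.

library(worrytype)

cfg <- dichotomy_config()

fx <- fixture_from_crosstabs()
fx_tabs <- build_group_tables(fx, cfg)
cat("fixture (printed cross-tabs), group counts:\n")
print(fx_tabs$groups[, c("worry_group", "n", "pct")])

w2 <- read_wave("results/sim/wave2.csv", wave = 2)
tabs <- build_group_tables(w2, cfg)
cat(sprintf("\nsynthetic wave 2 (n=%d classified):\n", tabs$n_classified))
print(tabs$groups[, c("worry_group", "n", "pct")])

# simplified two-group variant for comparison: ignores precautions
simp <- classify_simplified(w2, cfg)
cat("\nsimplified scheme on synthetic wave 2:\n")
print(table(simp$worry_group))

dir.create("results", showWarnings = FALSE)
write_outputs(list(
  fixture_groups = fx_tabs$groups,
  fixture_worry_precautions = fx_tabs$worry_precautions,
  fixture_precautions_qol = fx_tabs$precautions_qol,
  sim_groups_wave2 = tabs$groups,
  sim_classification_wave2 = cbind(respondent_id = w2$respondent_id,
                                   tabs$classification)), "results")
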