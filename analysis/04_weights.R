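#!/usr/bin/env Rscript
# Stage 4: quota weights on gender and age band. Targets here stand in for
# the census margins of the ten surveyed cities; weighted and unweighted
# group shares are reported side by side.

library(worrytype)

w2 <- read_wave("results/sim/wave2.csv", wave = 2)

targets <- margin_targets(
  gender = c(male = 0.48, female = 0.52),
  age_band = c("16-24" = 0.14, "25-44" = 0.41, "45-64" = 0.31, "65+" = 0.14))

wts <- compute_weights(w2, targets, mode = "cell")
w2$worry_group <- classify_full(w2)$worry_group
shares <- weighted_counts(w2, wts, by = "worry_group")

cat("worry-group shares, unweighted vs quota-weighted:\n")
print(cbind(shares[, c("group", "n")], round(shares[, c("pct", "weighted_pct")], 1)))
cat(sprintf("weight range: %.3f-%.3f, sum %.1f (sum-preserving)\n",
            min(wts$weight), max(wts$weight), sum(wts$weight)))

# raking on the same margins should agree to numerical precision here
wts_rake <- compute_weights(w2, targets, mode = "raking")
cat(sprintf("max |cell - raking| weight difference: %.2e\n",
            max(abs(wts$weight - wts_rake$weight))))

write_outputs(list(weights_wave2 = wts, groups_weighted = shares), "results")
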