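---
title: "Measuring functional and dysfunctional worry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional and dysfunctional worry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worrytype)
```

## The measurement problem

Worry about catching an infectious disease can be adaptive — prompting
precautions that restore a sense of safety — or corrosive, degrading quality
of life directly or through burdensome precautionary behaviour. A single
worry-intensity item cannot separate the two. `worrytype` implements a
rule-based typology that does, using four ingredients measured per
respondent per wave: the worry screener, a precaution screener, a five-point
"did the precautions make you feel safer" item, and two five-point
quality-of-life impact items (impact of the worry; impact of the
precautions).

The classification logic, in decision order:

1. screener missing → `unclassifiable`;
2. not worried → `unworried`, regardless of every other answer — worry is
   the entry condition of the typology, so precaution behaviour and
   quality-of-life impact among the unworried are deliberately ignored;
3. among the worried, **functional** requires all three of: precautions
   taken, precautions making the respondent feel safer, and none-or-little
   quality-of-life impact from *both* items;
4. everything else among the worried is **dysfunctional**, with a
   `rationale_code` recording the first failing condition (no precautions,
   not feeling safer, feel-safer unanswered, quality of life reduced).

Every record receives exactly one label, so on complete-answer data the
three groups partition the sample — a property the test suite checks on
randomly generated records.

## Cut points and their configurability

Two ordinal dichotomies sit under the rules, both held in
`dichotomy_config()`:

* `feel_safer_positive` — which feel-safer answers count as "the precautions
  made them feel safer". Default: the top three of five levels
  ("moderately", "quite a bit", "very much"). This matches the reported
  share of precaution-takers feeling safer (81% at "moderately" or above),
  but the published precaution cross-tab counts only 5 of 646
  precaution-takers as not feeling safer, which would suggest a laxer cut.
  The two statistics cannot be reconciled from the published material, so
  the cut is configurable and the default documents itself via
  `rationale_code`s rather than pretending the ambiguity away.
* `qol_low` — which quality-of-life answers count as "none or little"
  impact. Default: the bottom two of five levels. The dichotomy's name is
  published; the underlying scale points are a reconstruction.

Both sets must be threshold-like (upward- respectively downward-closed in
the ordinal order); the constructor enforces this.

**Missing data.** The published cell layout treats precaution-takers who
skipped the feel-safer item as dysfunctional; the package follows that rule
unconditionally. Worried respondents with unresolvable missing
quality-of-life answers follow `missing_qol_policy`
(default `"dysfunctional"`, mirroring the feel-safer treatment; switchable
to `"unclassifiable"` for sensitivity analysis). A missing answer on one
quality-of-life item is resolved by the other when that other answer alone
establishes some-or-strong impact.

The simplified scheme (`classify_simplified()`) splits the worried purely on
the worry-impact item. Whenever a full-scheme functional respondent answered
that item in the low band, the simplified scheme also calls them functional,
so simplified-functional is a superset of full-functional — tested as an
invariant.

## Derived indices

* **Adversity (impact) score** — count of eight binary adversity indicators
  (own and household job loss, unpayable bills, inaccessible food or
  medication, lost accommodation, close person hospitalised or died). A
  formative index: a sum of possibly unrelated misfortunes, not a latent
  construct. Infection history stays out of the index because it enters
  models as a separate predictor. Missing indicators count 0 and are
  flagged, since an unreported adversity is treated as absent rather than
  unknown.
* **Emotion score** — sum of six five-point items (anxiety, anger,
  loneliness, happiness, worthwhile, satisfied) after reverse-keying the
  three positive items, so 6 = best, 30 = worst. Missing items void the
  score; nothing is imputed. Reliability is reported with Cronbach's alpha,
  implemented from the item/total-variance formula and tested to 1e-12
  against an independent covariance-matrix computation.
* **Re-engagement score** — wave-3 minus wave-2 total over the three
  compliance-behaviour items (0–4 frequency each). Positive = more activity
  after restrictions eased; 0 = no change. The published description wavers
  between "the compliance item" and "the compliance items"; the package
  implements sum-minus-sum and also emits per-activity differences so either
  reading can be inspected.
* **Risk-perception recodes** — integer codes of the likelihood / control /
  severity triad in codebook order. Any monotone relabelling of the levels
  leaves model rank order unchanged.

## Quota weighting

`compute_weights()` aligns the gender and age-band margins to supplied
population targets. Cell mode (default) uses the exact ratio
target-share / sample-share per gender × age cell — when joint targets are
not supplied the independence product of the margins is used. Raking mode
runs iterative proportional fitting to a worst-margin error below 1e-8
(100-sweep cap). Whether the original study used joint cells or separate
margins is not stated, which is why both exist; on consistent targets they
agree to the tolerance, and this is tested.

Weighted totals in the source tables are visibly not normalised to the
sample size, so the normalisation total is an explicit target field,
defaulting to sum-preserving (weights sum to n). Published weighted counts
are *not* reproduction targets: the weight-calculation footnote is not part
of the available material, so population targets are user configuration and
only the mathematical properties of the weights (margin match, positivity,
scale invariance of percentages) are asserted.

## Transitions

`transitions()` classifies both waves of a linked panel, keeps respondents
present and classifiable in both, and reports the 3×3 count matrix, the
row-stochastic probability matrix, and the stability share
(trace / linked n). One-wave-only and unclassifiable respondents are counted
and excluded; attrition handling in the source figure is unstated, so
exclusion-with-reporting is the package's choice. The split is computed
unweighted by default (whether the published 71%/29% split was weighted is
unstated) with a weights option.

## Association models

`fit_model()` wraps the four estimation families behind one declarative
interface with listwise deletion and per-model n: multinomial logit
(`nnet::multinom`), negative binomial (`MASS::glm.nb`), Poisson and linear
(`stats`). Multinomial and negative-binomial estimates are reported
exponentiated (relative-risk / rate ratios) with log-scale standard errors;
Poisson and linear report raw coefficients — matching the conventions of the
published tables. Non-convergence and rank-deficient designs are hard
errors, never silent. Attitudinal covariate blocks are collapsed by
`pca_block_score()`: first principal component of the standardised items,
scores standardised and sign-aligned with the mean loading. Adversity
scores enter models as the raw 0–8 count, and risk-perception predictors as
integer-coded ordinals; neither scaling is stated in the published tables,
so the simplest one is used and documented.

A reference-switch invariant is tested: refitting a multinomial model with a
different reference category reproduces the implied ratio algebra to 1e-6
(the fitter is run to `reltol = 1e-14` so numerical optimisation error stays
well below that).

## The synthetic panel generator

There is no public unit-record data, so `generate_panel()` produces panels
with the statistical structure the analyses assume. Defaults are the study
conditions: 1100 wave-2 respondents, retention 1019/1100 (missing completely
at random — no attrition mechanism is published), group shares 401/203/487
out of 1091 classified (the published percentages 37/19/45 round from these
counts; the counts are used because they sum to 1 exactly), transition
kernel with diagonal 0.71 and movers split equally between the other two
groups (only the stay-share is published), adversity indicator rates
14/10/6/0.4/5/2/3/3 percent, and a had-COVID rate of 171/1100 (the only
published infection-history count; a generator choice).

Generation is structural, in causal order:

1. demographics, infection history and the eight adversity indicators are
   drawn from their marginals (demographic margins are generator choices at
   plausible UK-online-panel values);
2. the wave-2 group follows a multinomial logit in had-COVID and the
   adversity count with the configured relative-risk ratios (2.439/1.012 and
   0.979/1.465, functional/dysfunctional vs unworried). The two intercepts
   are calibrated deterministically before sampling: the adversity count
   distribution is an eight-term Poisson binomial computed by convolution,
   so the marginal group shares can be matched exactly by a fixed-point
   iteration over the enumerable 2 × 9 covariate cells. Fitting the same
   multinomial model to generated data therefore recovers the configured
   ratios, which is what the 200-replicate coverage check exercises;
3. the wave-3 group follows the transition kernel;
4. answer items are filled *within the defining cell of each group* — e.g. a
   dysfunctional respondent first draws which defining cell they occupy
   (quality-of-life-affected precaution-taker, no precautions, precautions
   without feeling safer, feel-safer unanswered) at the published cell
   frequencies — so the classifier recovers the latent group with zero
   error. That label fidelity is an invariant, not a statistical property.

**Emotion items.** The six items must jointly satisfy three published
facts: group means 14.312 × {1, 0.913, 1.164}, roughly negative-binomial
dispersion (theta 151.136), and item internal consistency near alpha 0.88.
The generator draws the total score as 6 + NB(mean − 6, theta*), with
theta* set per group so the total-score variance equals that of
NB(mean, 151.136) — the naive shift would leave the score underdispersed
relative to the fitted model. Scores are clipped to the feasible [6, 30]
(the clip probability is negligible at these means) and spread onto six 1–5
items by balanced allocation: each item gets the integer share and a random
subset gets the remainder, so items differ by at most one point. Balanced
profiles alone are too consistent (alpha ≈ 0.94), so a sum-preserving random
point transfer (probability 0.5 per respondent) roughens them; this rate was
calibrated by simulation to put alpha near 0.88 at n ≈ 1100. Items are
stored on their asked scales, positive items reversed, so the scoring
function's reverse-keying is exercised.

**Risk perception.** Only the ordering across groups is published
(dysfunctional: highest likelihood and severity, lowest control), so the
generator uses discretised normal draws around group means chosen to realise
that ordering at moderate effect sizes; the means are config, not fact.
Compliance items are binomial(4) frequencies with a higher wave-3 rate,
giving the re-engagement score a positive mean after restrictions ease.
Attitudinal blocks are one-factor items so the principal-component scoring
has real structure to find.

## Numerical choices and problem sizes

* Classification, scoring and weighting are exact arithmetic; the only
  tolerances are the raking stop (1e-8) and margin assertions (1e-6).
* Alpha is undefined at zero total variance and raises an error rather than
  returning NaN.
* Transition probability rows with zero count are NaN and flagged
  `undefined_rows` rather than silently renormalised.
* The test suite runs the deterministic fixture (1091 records) exactly;
  stochastic checks use n = 10,000 single panels for kernel and marginal
  calibration (3 binomial/Monte-Carlo standard-error bands) and 200
  replicates at n = 1058 for multinomial CI coverage and null size —
  problem sizes chosen to keep sampling error well inside the asserted
  bands while the whole suite stays in the tens of seconds.
* All randomness flows from a single integer seed per generator config;
  identical configs give byte-identical panels.

## Limitations

The generator emulates the *structure* the analyses assume, not real survey
behaviour: items are conditionally independent given the group beyond the
modelled blocks, attrition is random, demographics do not predict worry, and
city effects are pure noise. Passing recovery tests therefore shows the
estimators and pipeline are correct under the stated model, not that the
substantive findings would replicate on new data. Published regression
coefficients and weighted counts from the original microdata are not
reproducible without that microdata and are deliberately not targets; the
deterministic classification counts are, and are reproduced exactly from the
published cross-tabulations.
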