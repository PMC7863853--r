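# worrytype

Measurement tools for distinguishing **functional** from **dysfunctional**
worry about catching COVID-19 in two-wave survey panels, following the
functional-fear tradition of fear-of-crime research.

Public-health surveys usually measure worry about infection as a single
intensity. But worry is not uniformly harmful: for some people it motivates
precautions that make them feel safer at no cost to their quality of life,
while for others the worry and/or the precautions themselves erode daily
life. `worrytype` implements a rule-based typology that separates these
cases, together with everything needed to analyse it in a longitudinal
panel: codebook-validated survey input, derived psychometric indices, quota
weighting, wave-to-wave transition matrices, association models, and a
seeded synthetic panel generator so the entire pipeline is testable without
access to restricted survey microdata. It is aimed at survey methodologists
and epidemiologists working with risk-perception panels.

## The classification scheme

Each respondent in a wave is assigned exactly one label from the worry
screener ("have you felt worried about getting COVID-19 in the past 3
weeks?") and its follow-ups:

* **unworried** — answered "no" to the screener; nothing else matters;
* **functional** — worried **and** took precautions **and** the precautions
  made them feel safer (top of the five-point scale: "moderately", "quite a
  bit" or "very much") **and** quality of life had none-or-little impact
  from *both* the worry and the precautions;
* **dysfunctional** — worried, and any functional condition fails: no
  precautions, precautions that did not help (including not answering the
  feel-safer item), or quality of life reduced by worry and/or precautions.

A respondent with a missing screener is `unclassifiable`. A simplified
two-group variant (`classify_simplified()`) drops the precaution items and
splits the worried purely on whether worry reduces quality of life.

Downstream, group membership is analysed with multinomial logistic
regression (reported as relative-risk ratios), wellbeing with a negative
binomial GLM on a summative six-item emotion score (positive items
reverse-keyed, range 6–30), compliance with Poisson models using
principal-component scores of attitudinal item blocks, and re-engagement
with linear models on the wave-3 minus wave-2 compliance total.

## Worked example

```r
library(worrytype)

cfg   <- generator_config(seed = 20260924L)  # study-scale defaults: n = 1100
panel <- generate_panel(cfg)

tabs <- build_group_tables(panel$wave2)
tabs$groups
#>     worry_group   n  pct weighted_n weighted_pct
#> 1     unworried 419 38.1        419         38.1
#> 2    functional 203 18.5        203         18.5
#> 3 dysfunctional 478 43.5        478         43.5

tr <- transitions(link_panel(panel$wave2, panel$wave3))
tr
#> <transition_matrix> n_linked=1022 (excluded 0), stability=0.726
#>                wave3
#> wave2           unworried functional dysfunctional
#>   unworried         0.739      0.136         0.125
#>   functional        0.083      0.771         0.146
#>   dysfunctional     0.148      0.157         0.696

cronbach_alpha(emotion_item_matrix(panel$wave2))
#> [1] 0.8962685
```

About 38% of this synthetic wave are unworried, 19% functionally and 43%
dysfunctionally worried — the generator's defaults place the three groups at
the shares observed in the study the package models. Roughly 73% of linked
respondents keep their group between waves (the generating kernel holds 71%
in place), and the six emotion items show internal consistency near
alpha = 0.89.

The numbered scripts under `analysis/` run the full workflow — simulate,
classify, score, weight, estimate transitions, fit models — writing tables
to `results/`:

```sh
Rscript analysis/01_simulate.R   # ... through analysis/06_models.R
```

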