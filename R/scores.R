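#' COVID adversity (impact) score
#'
#' A formative index: the count of the eight binary adversity indicators a
#' respondent reported (job loss, household job loss, unable to pay bills,
#' unable to access food or medication, lost accommodation, close person
#' hospitalised, close person died). Higher scores mean the respondent was
#' more severely affected. Infection history (`had_covid`,
#' `suspected_covid`) is deliberately *not* part of the index — it enters
#' models as a separate predictor.
#'
#' Missing indicators count as 0 (no reported adversity); the number of
#' missing components is returned alongside so callers can flag or filter.
#'
#' @param data wave table containing the eight `exp_*` columns.
#' @return Data frame with columns `impact_score` (integer 0-8) and
#'   `n_missing_components`.
#' @export
covid_impact_score <- function(data) {
  items <- experience_items()
  absent <- setdiff(items, names(data))
  if (length(absent)) stop("missing experience columns: ", paste(absent, collapse = ", "))
  m <- sapply(items, function(it) as.character(data[[it]]) == "yes")
  m <- matrix(m, nrow = nrow(data))
  data.frame(impact_score = as.integer(rowSums(m, na.rm = TRUE)),
             n_missing_components = as.integer(rowSums(is.na(m))))
}

#' Binary recode of one emotion item
#'
#' Dichotomises a five-point emotion item so that `"yes"` always marks a bad
#' emotional outcome. For the negative emotions (anxiety, anger, loneliness)
#' everyone except "not at all" is `"yes"`; for the positively keyed items
#' (happiness, worthwhile, satisfied) only "not at all" — never happy, never
#' worthwhile, not at all satisfied — is `"yes"`.
#'
#' @param item character vector of five-point levels (or `NA`).
#' @param item_name one of the six emotion item names (see codebook).
#' @return Character vector of `"yes"`/`"no"`/`NA`.
#' @export
recode_emotion_binary <- function(item, item_name) {
  if (!item_name %in% emotion_items())
    stop("unknown emotion item: ", item_name)
  floor_level <- item == "not at all"
  out <- if (item_name %in% emotion_positive_items()) {
    ifelse(floor_level, "yes", "no")
  } else {
    ifelse(floor_level, "no", "yes")
  }
  out[is.na(item)] <- NA_character_
  out
}

#' Summative emotion score
#'
#' Sums the six emotion / life-evaluation items after recoding each to run
#' 1-5 with higher = worse: the three positive items (happiness, worthwhile,
#' satisfied) are reverse-keyed. The score ranges 6 (best possible) to 30
#' (worst possible). Records with any missing item get `NA` — the score is
#' never imputed.
#'
#' @param data wave table containing the six `emo_*` columns.
#' @param likert_levels ordered response levels of the emotion items.
#' @return Integer vector of scores (`NA` where any item is missing).
#' @export
emotion_score <- function(data, likert_levels = c("not at all", "a little", "moderately",
                                                  "quite a bit", "very much")) {
  mat <- emotion_item_matrix(data, likert_levels)
  out <- as.integer(rowSums(mat))
  out
}

#' Recoded emotion item matrix
#'
#' The six emotion items as integers 1-5 with higher = worse (positive items
#' reverse-keyed). This is the matrix the summative score sums over and the
#' reliability coefficient is computed from.
#'
#' @inheritParams emotion_score
#' @return Integer matrix `nrow(data)` x 6 with the item names as columns;
#'   `NA` where an item is missing.
#' @export
emotion_item_matrix <- function(data, likert_levels = c("not at all", "a little", "moderately",
                                                        "quite a bit", "very much")) {
  items <- emotion_items()
  absent <- setdiff(items, names(data))
  if (length(absent)) stop("missing emotion columns: ", paste(absent, collapse = ", "))
  k <- length(likert_levels)
  mat <- sapply(items, function(it) {
    v <- match(as.character(data[[it]]), likert_levels)
    if (it %in% emotion_positive_items()) v <- k + 1L - v  # reverse-key: higher = worse
    v
  })
  matrix(as.integer(mat), nrow = nrow(data), dimnames = list(NULL, items))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a set of items:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i \sigma^2_i}{\sigma^2_{total}}\right)}
#' where \eqn{\sigma^2_i} are the item variances and \eqn{\sigma^2_{total}}
#' the variance of the summative score.
#'
#' @param item_matrix numeric matrix, respondents in rows, items in columns;
#'   rows with any missing value are dropped.
#' @return Alpha in \eqn{(-\infty, 1]}.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 complete rows to compute alpha")
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items to compute alpha")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("total score has zero variance; alpha is undefined")
  item_var <- apply(m, 2, stats::var)
  (k / (k - 1)) * (1 - sum(item_var) / total_var)
}

#' Re-engagement change score
#'
#' The wave-3 compliance-behaviour total minus the wave-2 total for each
#' linked respondent. During wave 2 the three behaviours (socialising outside
#' the household; walking/running/cycling and sitting to relax; travelling
#' for leisure) breached lockdown rules; by wave 3 they were permitted, so a
#' positive change reads as re-engagement with social and economic life, 0 as
#' no change, and a negative score as more engagement in wave 2 than wave 3.
#'
#' @param panel a `panel_table` from [link_panel()], or a list with validated
#'   `wave2` and `wave3` tables.
#' @return Data frame with one row per both-waves respondent: the summed
#'   totals (`w2_total`, `w3_total`), the change score `value`
#'   (= `w3_total - w2_total`, `NA` when any activity item is missing in
#'   either wave), and per-activity differences `d_<item>`.
#' @export
reengagement_score <- function(panel) {
  items <- compliance_items()
  w2 <- panel$wave2
  w3 <- panel$wave3
  ids <- intersect(w2$respondent_id, w3$respondent_id)
  i2 <- match(ids, w2$respondent_id)
  i3 <- match(ids, w3$respondent_id)
  m2 <- sapply(items, function(it) as.numeric(w2[[it]][i2]))
  m3 <- sapply(items, function(it) as.numeric(w3[[it]][i3]))
  m2 <- matrix(m2, nrow = length(ids)); m3 <- matrix(m3, nrow = length(ids))
  out <- data.frame(respondent_id = ids,
                    w2_total = rowSums(m2),
                    w3_total = rowSums(m3))
  out$value <- out$w3_total - out$w2_total
  diffs <- m3 - m2
  colnames(diffs) <- paste0("d_", items)
  cbind(out, as.data.frame(diffs))
}

#' Integer coding of the risk-perception triad
#'
#' Pass-through recode of the three risk-perception items (perceived
#' likelihood of catching COVID-19 in the next three weeks, perceived control
#' over catching it, perceived severity of consequences to health) onto
#' their codebook-ordered integer codes: higher = more likely / more control /
#' more severe.
#'
#' @param data wave table with `risk_likelihood`, `risk_control`,
#'   `risk_severity` columns.
#' @param likert_levels ordered response levels of the risk items.
#' @return Data frame with integer columns `likelihood`, `control`,
#'   `severity` (`NA` where missing).
#' @export
recode_risk_perception <- function(data, likert_levels = c("not at all", "a little", "moderately",
                                                           "quite a bit", "very much")) {
  code <- function(x) match(as.character(x), likert_levels)
  data.frame(likelihood = code(data$risk_likelihood),
             control = code(data$risk_control),
             severity = code(data$risk_severity))
}
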