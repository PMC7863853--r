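#' Configuration of the dichotomies behind the worry typology
#'
#' Two cut points drive the classification: which "feel safer" answers count
#' as precautions actually making the respondent feel safer, and which
#' quality-of-life answers count as "none or little" impact. Both are
#' configurable because the underlying response scale points are survey
#' choices, not part of the typology itself.
#'
#' @param feel_safer_positive levels of `feel_safer` treated as feeling safer;
#'   must be a nonempty upward-closed set of the five ordered levels. Default
#'   is the top three ("moderately", "quite a bit", "very much").
#' @param qol_low levels of the quality-of-life items counted as "none or
#'   little" impact; must be downward-closed. Default is the bottom two.
#' @param missing_qol_policy what to do with worried respondents whose
#'   quality-of-life answers are missing (and cannot be resolved by the other
#'   item): `"dysfunctional"` (default, mirroring the treatment of the
#'   missing feel-safer cell) or `"unclassifiable"`.
#' @param likert_levels the ordered five-point scale the cut points refer to.
#' @return A list of class `dichotomy_config`.
#' @export
dichotomy_config <- function(feel_safer_positive = c("moderately", "quite a bit", "very much"),
                             qol_low = c("not at all", "a little"),
                             missing_qol_policy = c("dysfunctional", "unclassifiable"),
                             likert_levels = c("not at all", "a little", "moderately",
                                               "quite a bit", "very much")) {
  missing_qol_policy <- match.arg(missing_qol_policy)
  if (!length(feel_safer_positive)) stop("feel_safer_positive must be nonempty")
  pos_idx <- match(feel_safer_positive, likert_levels)
  low_idx <- match(qol_low, likert_levels)
  if (anyNA(pos_idx)) stop("feel_safer_positive contains unknown levels")
  if (anyNA(low_idx)) stop("qol_low contains unknown levels")
  # upward/downward closure keeps the cut points interpretable as thresholds
  if (!setequal(pos_idx, seq(min(pos_idx), length(likert_levels))))
    stop("feel_safer_positive must be upward-closed in the ordinal order")
  if (length(low_idx) && !setequal(low_idx, seq_len(max(low_idx))))
    stop("qol_low must be downward-closed in the ordinal order")
  structure(list(feel_safer_positive = feel_safer_positive,
                 qol_low = qol_low,
                 missing_qol_policy = missing_qol_policy,
                 likert_levels = likert_levels),
            class = "dichotomy_config")
}

#' Group labels in their fixed reporting order
#' @return Character vector `c("unworried", "functional", "dysfunctional")`.
#' @export
worry_groups <- function() c("unworried", "functional", "dysfunctional")

#' Combined quality-of-life impact of worry and precautions
#'
#' Collapses the two quality-of-life items (impact of worry, impact of
#' precautions) into the dichotomy used by the typology: "none or little
#' effect of both" versus "some or strong effect of either or both".
#'
#' @param qol_worry,qol_precautions character vectors of five-point levels
#'   (or `NA`).
#' @param cfg a [dichotomy_config()].
#' @return Factor with levels `none_or_little_both`, `some_or_strong_either`,
#'   `missing`. A record is `missing` only when an item is unanswered and the
#'   other answered item cannot already establish some-or-strong impact.
#' @export
combined_qol_impact <- function(qol_worry, qol_precautions, cfg = dichotomy_config()) {
  w_low <- qol_worry %in% cfg$qol_low
  p_low <- qol_precautions %in% cfg$qol_low
  w_high <- !is.na(qol_worry) & !w_low
  p_high <- !is.na(qol_precautions) & !p_low
  out <- rep("missing", length(qol_worry))
  out[w_high | p_high] <- "some_or_strong_either"
  out[w_low & p_low] <- "none_or_little_both"
  factor(out, levels = c("none_or_little_both", "some_or_strong_either", "missing"))
}

group_factor <- function(x) {
  factor(x, levels = c(worry_groups(), "unclassifiable"))
}

#' Classify respondents into worry groups (full scheme)
#'
#' The three-group typology of worry about catching COVID-19:
#'
#' * **unworried** — said "no" to the worry screener, regardless of every
#'   other answer (including taking precautions or reduced quality of life);
#' * **functional** — worried, took precautions, the precautions made them
#'   feel safer, and quality of life had none-or-little impact from both the
#'   worry and the precautions;
#' * **dysfunctional** — worried, and any of: took no precautions,
#'   precautions did not make them feel safer (including not answering the
#'   feel-safer item), or quality of life reduced by worry and/or precautions.
#'
#' Respondents whose worry screener is missing are `unclassifiable`; worried
#' respondents with missing quality-of-life answers follow
#' `cfg$missing_qol_policy`.
#'
#' @param data a validated wave table (or data frame with columns `worried`,
#'   `takes_precautions`, `feel_safer`, `qol_worry`, `qol_precautions`).
#' @param cfg a [dichotomy_config()].
#' @return A data frame with columns `worry_group` (factor: unworried,
#'   functional, dysfunctional, unclassifiable) and `rationale_code`
#'   (which rule fired), aligned row-by-row with `data`.
#' @export
classify_full <- function(data, cfg = dichotomy_config()) {
  n <- nrow(data)
  worried <- as.character(data$worried)
  prec <- as.character(data$takes_precautions)
  safer <- as.character(data$feel_safer)
  qol <- combined_qol_impact(data$qol_worry, data$qol_precautions, cfg)

  group <- rep(NA_character_, n)
  why <- rep(NA_character_, n)

  assign_rule <- function(cond, g, code) {
    take <- is.na(group) & cond & !is.na(cond)
    group[take] <<- g
    why[take] <<- code
  }

  assign_rule(is.na(worried), "unclassifiable", "worry_missing")
  assign_rule(worried == "no", "unworried", "not_worried")
  # remaining records are worried; rules ordered so the first failing
  # condition of the functional definition is recorded as the rationale
  qol_missing_group <- if (cfg$missing_qol_policy == "dysfunctional")
    "dysfunctional" else "unclassifiable"
  assign_rule(is.na(prec), qol_missing_group, "precautions_missing")
  assign_rule(prec == "no", "dysfunctional", "no_precautions")
  assign_rule(is.na(safer), "dysfunctional", "safer_missing")
  assign_rule(!safer %in% cfg$feel_safer_positive, "dysfunctional", "not_safer")
  assign_rule(qol == "some_or_strong_either", "dysfunctional", "qol_reduced")
  assign_rule(qol == "missing", qol_missing_group, "qol_missing")
  assign_rule(rep(TRUE, n), "functional", "all_three_conditions")

  data.frame(worry_group = group_factor(group), rationale_code = why)
}

#' Classify respondents into worry groups (simplified scheme)
#'
#' The reduced-item variant for resource-constrained surveys: precaution
#' items are ignored entirely, and worried respondents are split on whether
#' their worry alone reduces their quality of life. Unworried respondents are
#' classified exactly as in the full scheme.
#'
#' @inheritParams classify_full
#' @return Same shape as [classify_full()].
#' @export
classify_simplified <- function(data, cfg = dichotomy_config()) {
  n <- nrow(data)
  worried <- as.character(data$worried)
  qw <- as.character(data$qol_worry)

  group <- rep(NA_character_, n)
  why <- rep(NA_character_, n)
  assign_rule <- function(cond, g, code) {
    take <- is.na(group) & cond & !is.na(cond)
    group[take] <<- g
    why[take] <<- code
  }
  qol_missing_group <- if (cfg$missing_qol_policy == "dysfunctional")
    "dysfunctional" else "unclassifiable"

  assign_rule(is.na(worried), "unclassifiable", "worry_missing")
  assign_rule(worried == "no", "unworried", "not_worried")
  assign_rule(is.na(qw), qol_missing_group, "qol_missing")
  assign_rule(!qw %in% cfg$qol_low, "dysfunctional", "qol_reduced")
  assign_rule(rep(TRUE, n), "functional", "qol_unaffected")

  data.frame(worry_group = group_factor(group), rationale_code = why)
}

#' Build the worry/precaution/quality-of-life summary tables
#'
#' Produces the three summary tables that document the classification of one
#' wave: (i) worried respondents broken down by precautionary activity and
#' feeling safer, with the unworried count alongside; (ii) the precaution
#' rows crossed with the combined quality-of-life dichotomy, flagging the
#' functional cell; (iii) group counts and percentages. When `weights` are
#' supplied each table also carries weighted counts and percentages.
#'
#' @param data a validated wave table.
#' @param cfg a [dichotomy_config()].
#' @param weights optional numeric vector of per-respondent weights, aligned
#'   with rows of `data`.
#' @return A list with elements `worry_precautions`, `precautions_qol`,
#'   `groups` (data frames), plus `n_classified` and `classification` (the
#'   per-record output of [classify_full()]).
#' @export
build_group_tables <- function(data, cfg = dichotomy_config(), weights = NULL) {
  cls <- classify_full(data, cfg)
  if (is.null(weights)) weights <- rep(1, nrow(data)) else stopifnot(length(weights) == nrow(data))

  worried <- !is.na(data$worried) & data$worried == "yes"
  prec <- as.character(data$takes_precautions)
  safer <- as.character(data$feel_safer)
  qol <- combined_qol_impact(data$qol_worry, data$qol_precautions, cfg)

  prec_cell <- rep(NA_character_, nrow(data))
  prec_cell[worried & !is.na(prec) & prec == "no"] <- "no_precautions"
  has_prec <- worried & !is.na(prec) & prec == "yes"
  prec_cell[has_prec & is.na(safer)] <- "precautions_safer_missing"
  prec_cell[has_prec & !is.na(safer) & safer %in% cfg$feel_safer_positive] <- "precautions_and_safer"
  prec_cell[has_prec & !is.na(safer) & !safer %in% cfg$feel_safer_positive] <- "precautions_not_safer"

  cell_levels <- c("no_precautions", "precautions_and_safer",
                   "precautions_not_safer", "precautions_safer_missing")
  count_by <- function(f, w, lev) {
    f <- factor(f, levels = lev)
    n <- as.integer(table(f))
    wn <- as.numeric(tapply(w, f, sum, default = 0))
    list(n = n, weighted_n = wn)
  }

  t1 <- count_by(prec_cell[worried], weights[worried], cell_levels)
  worry_precautions <- data.frame(
    cell = cell_levels, n = t1$n,
    pct = round(100 * t1$n / sum(t1$n), 1),
    weighted_n = t1$weighted_n,
    weighted_pct = round(100 * t1$weighted_n / sum(t1$weighted_n), 1))
  attr(worry_precautions, "n_unworried") <- sum(!is.na(data$worried) & data$worried == "no")
  attr(worry_precautions, "n_worried") <- sum(worried)

  # table 2 layout: merge no-precautions with precautions-not-safer
  row2 <- rep(NA_character_, nrow(data))
  row2[worried & prec_cell %in% c("no_precautions", "precautions_not_safer")] <-
    "no_precautions_or_not_safer"
  row2[worried & prec_cell == "precautions_and_safer"] <- "precautions_and_safer"
  row2[worried & prec_cell == "precautions_safer_missing"] <- "precautions_safer_missing"
  row_levels <- c("precautions_and_safer", "no_precautions_or_not_safer",
                  "precautions_safer_missing")
  tab <- table(factor(row2[worried], levels = row_levels),
               factor(qol[worried], levels = levels(qol)))
  wtab <- tapply(weights[worried], list(factor(row2[worried], levels = row_levels),
                                        factor(qol[worried], levels = levels(qol))),
                 sum, default = 0)
  precautions_qol <- data.frame(
    precaution_row = row_levels,
    none_or_little_both = as.integer(tab[, "none_or_little_both"]),
    some_or_strong_either = as.integer(tab[, "some_or_strong_either"]),
    qol_missing = as.integer(tab[, "missing"]),
    weighted_none_or_little_both = as.numeric(wtab[, "none_or_little_both"]),
    weighted_some_or_strong_either = as.numeric(wtab[, "some_or_strong_either"]),
    functional_cell = c(TRUE, FALSE, FALSE))

  classified <- cls$worry_group != "unclassifiable"
  g <- count_by(cls$worry_group[classified], weights[classified], worry_groups())
  groups <- data.frame(
    worry_group = worry_groups(), n = g$n,
    pct = round(100 * g$n / sum(g$n), 1),
    weighted_n = g$weighted_n,
    weighted_pct = round(100 * g$weighted_n / sum(g$weighted_n), 1))

  list(worry_precautions = worry_precautions,
       precautions_qol = precautions_qol,
       groups = groups,
       n_classified = sum(cls$worry_group != "unclassifiable", na.rm = TRUE),
       classification = cls)
}
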