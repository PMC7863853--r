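#' The default item codebook for the two-wave worry panel
#'
#' A codebook is a data frame with one row per questionnaire item, carrying
#' the item name, its measurement type, the ordered response levels, the
#' tokens treated as missing, and the waves in which the item was fielded.
#' Downstream operations (classification, scoring, model fitting) only ever
#' refer to items through the codebook, so alternative questionnaire wordings
#' can be accommodated by editing it.
#'
#' The default codebook is a reconstruction: the level labels follow the
#' five-point "not at all" ... "very much" response format common to this
#' family of surveys, since the original questionnaire appendix wording is
#' not available. Items covered:
#'
#' * worry screener (`worried`) plus frequency/intensity follow-ups;
#' * precautionary activity (`takes_precautions`, `feel_safer`) and the two
#'   quality-of-life impact items (`qol_worry`, `qol_precautions`);
#' * infection history (`had_covid`, `suspected_covid`) and eight binary
#'   adversity indicators (`exp_*`);
#' * six emotion / life-evaluation items (`emo_*`);
#' * three compliance-behaviour frequency items (`comp_*`, integer 0-4);
#' * the risk-perception triad (`risk_likelihood`, `risk_control`,
#'   `risk_severity`);
#' * covariate blocks: self-rated knowledge, deterrence, legal and police
#'   legitimacy, social norms, expressive function of the law;
#' * demographics (`age_band`, `gender`, `ethnicity`, `keyworker`, `city`).
#'
#' @param missing_codes character tokens interpreted as missing in raw CSVs.
#' @return A data frame of class `worry_codebook` with columns `item`,
#'   `type` (one of `"binary"`, `"likert5"`, `"count"`, `"categorical"`),
#'   `levels` (list column of ordered level labels; for counts the inclusive
#'   integer range as a length-2 integer vector), `missing_codes` (list
#'   column), and `waves` (list column of integer wave ids).
#' @export
default_codebook <- function(missing_codes = c("", "NA", "missing")) {
  lik5 <- c("not at all", "a little", "moderately", "quite a bit", "very much")
  yn <- c("no", "yes")
  freq3 <- c("once or twice", "three to ten times", "more than ten times")
  int4 <- c("not very worried", "a bit worried", "fairly worried", "very worried")
  cities <- c("Birmingham", "Cardiff", "Edinburgh", "Glasgow", "Leeds",
              "Liverpool", "London", "Manchester", "Newcastle", "Sheffield",
              "none of these")

  row <- function(item, type, levels, waves = c(2L, 3L)) {
    data.frame(item = item, type = type,
               levels = I(list(levels)),
               missing_codes = I(list(missing_codes)),
               waves = I(list(as.integer(waves))))
  }
  exp_items <- experience_items()
  emo <- emotion_items()
  comp <- compliance_items()
  blocks <- covariate_blocks()

  cb <- do.call(rbind, c(
    list(
      row("worried", "binary", yn),
      row("worry_frequency", "categorical", freq3),
      row("worry_intensity", "categorical", int4),
      row("qol_worry", "likert5", lik5),
      row("takes_precautions", "binary", yn),
      row("feel_safer", "likert5", lik5),
      row("qol_precautions", "likert5", lik5),
      row("had_covid", "binary", yn),
      row("suspected_covid", "binary", yn)
    ),
    lapply(exp_items, row, type = "binary", levels = yn),
    lapply(emo, row, type = "likert5", levels = lik5),
    lapply(comp, row, type = "count", levels = c(0L, 4L)),
    list(
      row("risk_likelihood", "likert5", lik5),
      row("risk_control", "likert5", lik5),
      row("risk_severity", "likert5", lik5),
      row("knowledge", "likert5", lik5)
    ),
    lapply(unlist(blocks, use.names = FALSE), row, type = "likert5", levels = lik5),
    list(
      row("age_band", "categorical", c("16-24", "25-44", "45-64", "65+")),
      row("gender", "categorical", c("male", "female")),
      row("ethnicity", "categorical", c("White", "BAME")),
      row("keyworker", "binary", yn),
      row("city", "categorical", cities)
    )
  ))
  rownames(cb) <- NULL
  class(cb) <- c("worry_codebook", "data.frame")
  validate_codebook(cb)
  cb
}

#' @export
print.worry_codebook <- function(x, ...) {
  cat(sprintf("<worry_codebook> %d items\n", nrow(x)))
  tab <- table(x$type)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  invisible(x)
}

# Internal consistency checks; stops on a malformed codebook.
validate_codebook <- function(cb) {
  stopifnot(is.data.frame(cb),
            all(c("item", "type", "levels", "missing_codes", "waves") %in% names(cb)))
  if (anyDuplicated(cb$item)) stop("duplicate item names in codebook")
  bad_type <- setdiff(unique(cb$type), c("binary", "likert5", "count", "categorical"))
  if (length(bad_type)) stop("unknown item types: ", paste(bad_type, collapse = ", "))
  for (i in seq_len(nrow(cb))) {
    lv <- cb$levels[[i]]
    mc <- cb$missing_codes[[i]]
    if (cb$type[i] == "likert5" && length(lv) != 5L)
      stop("likert5 item '", cb$item[i], "' must have exactly 5 levels")
    if (cb$type[i] == "binary" && length(lv) != 2L)
      stop("binary item '", cb$item[i], "' must have exactly 2 levels")
    if (cb$type[i] == "count" && length(lv) != 2L)
      stop("count item '", cb$item[i], "' must give an integer range c(lo, hi)")
    if (cb$type[i] != "count" && length(intersect(as.character(lv), mc)))
      stop("missing codes overlap levels for item '", cb$item[i], "'")
  }
  invisible(cb)
}

# Canonical item-name helpers reused across modules ---------------------------

experience_items <- function() {
  c("exp_self_job_loss", "exp_household_job_loss", "exp_unable_pay_bills",
    "exp_unable_access_food", "exp_unable_access_medication",
    "exp_lost_accommodation", "exp_close_hospitalised", "exp_close_died")
}

emotion_items <- function() {
  c("emo_anxiety", "emo_anger", "emo_loneliness",
    "emo_happiness", "emo_worthwhile", "emo_satisfied")
}

# Items keyed so that the raw top level is a GOOD outcome; these are
# reverse-coded when building the summative emotion score.
emotion_positive_items <- function() {
  c("emo_happiness", "emo_worthwhile", "emo_satisfied")
}

compliance_items <- function() {
  c("comp_socialised", "comp_exercise_relax", "comp_travel_leisure")
}

covariate_blocks <- function() {
  list(
    deterrence       = paste0("det_", 1:3),
    legal_legitimacy = paste0("leg_", 1:3),
    police_legitimacy = paste0("pol_", 1:3),
    social_norms     = paste0("norm_", 1:3),
    expressive_law   = paste0("expr_", 1:3)
  )
}

#' Read or write a codebook as YAML
#'
#' @param path file path.
#' @return `read_codebook()` returns a `worry_codebook` data frame;
#'   `write_codebook()` returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  cb <- do.call(rbind, lapply(raw$items, function(it) {
    lv <- if (identical(it$type, "count")) as.integer(it$levels) else as.character(it$levels)
    data.frame(item = it$item, type = it$type, levels = I(list(lv)),
               missing_codes = I(list(as.character(it$missing_codes))),
               waves = I(list(as.integer(it$waves))))
  }))
  rownames(cb) <- NULL
  class(cb) <- c("worry_codebook", "data.frame")
  validate_codebook(cb)
  cb
}

#' @rdname read_codebook
#' @param codebook a `worry_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  items <- lapply(seq_len(nrow(codebook)), function(i) {
    list(item = codebook$item[i], type = codebook$type[i],
         levels = codebook$levels[[i]],
         missing_codes = codebook$missing_codes[[i]],
         waves = codebook$waves[[i]])
  })
  yaml::write_yaml(list(items = items), path)
  invisible(path)
}

# Look up one codebook row; hard error when absent, because downstream
# operations must never reference an undocumented item.
codebook_entry <- function(codebook, item) {
  i <- match(item, codebook$item)
  if (is.na(i)) stop("item '", item, "' not present in codebook")
  list(item = codebook$item[i], type = codebook$type[i],
       levels = codebook$levels[[i]], missing_codes = codebook$missing_codes[[i]],
       waves = codebook$waves[[i]])
}
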