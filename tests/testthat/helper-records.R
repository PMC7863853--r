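# Shared helpers: minimal record builders used across test files.

lik5_levels <- c("not at all", "a little", "moderately", "quite a bit", "very much")

# A single classification record with sensible defaults, overridable per field.
worry_record <- function(worried = "yes", takes_precautions = "yes",
                         feel_safer = "very much", qol_worry = "not at all",
                         qol_precautions = "not at all") {
  data.frame(worried = worried, takes_precautions = takes_precautions,
             feel_safer = feel_safer, qol_worry = qol_worry,
             qol_precautions = qol_precautions, stringsAsFactors = FALSE)
}

# Random complete-answer classification records (all fields valid levels).
random_records <- function(n, seed = 42L) {
  set.seed(seed)
  data.frame(
    worried = sample(c("yes", "no"), n, TRUE),
    takes_precautions = sample(c("yes", "no"), n, TRUE),
    feel_safer = sample(lik5_levels, n, TRUE),
    qol_worry = sample(lik5_levels, n, TRUE),
    qol_precautions = sample(lik5_levels, n, TRUE),
    stringsAsFactors = FALSE)
}

# A tiny complete wave table (valid against the default codebook) for io tests.
small_wave_df <- function(n = 3L, ids = sprintf("p%02d", seq_len(n))) {
  cb <- default_codebook()
  out <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cb))) {
    lv <- cb$levels[[i]]
    out[[cb$item[i]]] <- if (cb$type[i] == "count")
      as.integer(seq_len(n) %% (lv[2] + 1L))
    else rep_len(lv, n)
  }
  out
}
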