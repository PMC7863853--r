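test_that("combined quality-of-life impact implements the two-item dichotomy", {
  cfg <- dichotomy_config()
  expect_equal(as.character(combined_qol_impact("not at all", "not at all", cfg)),
               "none_or_little_both")
  expect_equal(as.character(combined_qol_impact("not at all", "very much", cfg)),
               "some_or_strong_either")
  expect_equal(as.character(combined_qol_impact(NA, "not at all", cfg)), "missing")
  # one answered item above the low band settles the record even if the other
  # is missing
  expect_equal(as.character(combined_qol_impact(NA, "moderately", cfg)),
               "some_or_strong_either")
  expect_equal(as.character(combined_qol_impact(NA, NA, cfg)), "missing")
})

test_that("the full classifier applies the three-group rules", {
  cases <- rbind(
    # unworried wins over everything, even strong quality-of-life impact
    cbind(worry_record(worried = "no", qol_precautions = "very much"),
          want = "unworried", why = "not_worried"),
    # all three functional conditions met
    cbind(worry_record(), want = "functional", why = "all_three_conditions"),
    # precautions taken but feel-safer unanswered -> dysfunctional
    cbind(worry_record(feel_safer = NA), want = "dysfunctional", why = "safer_missing"),
    # no precautions, even with quality of life untouched -> dysfunctional
    cbind(worry_record(takes_precautions = "no", feel_safer = NA),
          want = "dysfunctional", why = "no_precautions"),
    # precautions did not make them feel safer
    cbind(worry_record(feel_safer = "a little"), want = "dysfunctional", why = "not_safer"),
    # quality of life reduced by either item
    cbind(worry_record(qol_worry = "quite a bit"), want = "dysfunctional", why = "qol_reduced"),
    # worry screener missing -> unclassifiable
    cbind(worry_record(worried = NA), want = "unclassifiable", why = "worry_missing"))
  got <- classify_full(cases)
  expect_equal(as.character(got$worry_group), cases$want)
  expect_equal(got$rationale_code, cases$why)
})

test_that("missing quality-of-life answers among the worried follow the policy", {
  rec <- worry_record(qol_worry = NA, qol_precautions = NA)
  expect_equal(as.character(classify_full(rec)$worry_group), "dysfunctional")
  cfg <- dichotomy_config(missing_qol_policy = "unclassifiable")
  expect_equal(as.character(classify_full(rec, cfg)$worry_group), "unclassifiable")
})

test_that("the simplified classifier ignores precautions entirely", {
  # worried, quality of life untouched, but NO precautions: simplified says
  # functional where the full scheme says dysfunctional
  rec <- worry_record(takes_precautions = "no", feel_safer = NA)
  expect_equal(as.character(classify_simplified(rec)$worry_group), "functional")
  expect_equal(as.character(classify_full(rec)$worry_group), "dysfunctional")
  expect_equal(as.character(classify_simplified(worry_record(qol_worry = "very much"))$worry_group),
               "dysfunctional")
  expect_equal(as.character(classify_simplified(worry_record(worried = "no"))$worry_group),
               "unworried")
})

test_that("simplified-functional contains full-functional on complete records", {
  recs <- random_records(500, seed = 9L)
  full <- classify_full(recs)$worry_group
  simp <- classify_simplified(recs)$worry_group
  expect_true(all(simp[full == "functional"] == "functional"))
})

test_that("dichotomy cut points validate closure and stay configurable", {
  expect_error(dichotomy_config(feel_safer_positive = c("a little", "very much")),
               "upward-closed")
  expect_error(dichotomy_config(qol_low = "a little"), "downward-closed")
  # the stricter feel-safer cut shifts not-safer records into dysfunctional
  cfg_strict <- dichotomy_config(feel_safer_positive = c("quite a bit", "very much"))
  rec <- worry_record(feel_safer = "moderately")
  expect_equal(as.character(classify_full(rec)$worry_group), "functional")
  expect_equal(as.character(classify_full(rec, cfg_strict)$worry_group), "dysfunctional")
})

test_that("group tables: all-unworried wave collapses to a single group", {
  recs <- random_records(50, seed = 3L)
  recs$worried <- "no"
  tabs <- build_group_tables(recs)
  expect_equal(tabs$groups$n, c(50L, 0L, 0L))
})

test_that("table-2 cell counts partition the worried total of table 1", {
  recs <- random_records(800, seed = 5L)
  tabs <- build_group_tables(recs)
  n_worried <- attr(tabs$worry_precautions, "n_worried")
  expect_equal(sum(tabs$worry_precautions$n), n_worried)
  t2 <- tabs$precautions_qol
  expect_equal(sum(t2$none_or_little_both + t2$some_or_strong_either + t2$qol_missing),
               n_worried)
})
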