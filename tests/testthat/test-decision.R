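lr <- function(specimen_label = "A", diagnosis_class = "bcc",
               excision_type = "excision", peripheral_margin = "clear",
               deep_margin = "clear", recurrent = FALSE,
               supplemental = FALSE, ...) {
  lesion_record(specimen_label = specimen_label,
                diagnosis_class = diagnosis_class,
                excision_type = excision_type,
                peripheral_margin = peripheral_margin,
                deep_margin = deep_margin, recurrent = recurrent,
                supplemental = supplemental, ...)
}

test_that("lesion classification follows the guideline rows", {
  expect_equal(classify_lesion_outcome(lr())$code, "complete_single_bcc")
  expect_equal(classify_lesion_outcome(
    lr(peripheral_margin = "involved"))$code, "incomplete_bcc")
  expect_equal(classify_lesion_outcome(
    lr(deep_margin = "involved"))$code, "incomplete_bcc")
  expect_equal(classify_lesion_outcome(lr(recurrent = TRUE))$code,
               "recurrent_bcc")
  expect_equal(classify_lesion_outcome(
    lr(excision_type = "punch_biopsy"))$code, "diagnostic_biopsy_bcc")
  expect_equal(classify_lesion_outcome(
    lr(diagnosis_class = "benign"))$code, "benign_or_non_specific")
  expect_equal(classify_lesion_outcome(
    lr(diagnosis_class = "non_specific", excision_type = "unknown",
       peripheral_margin = "not_stated", deep_margin = "not_stated"))$code,
    "benign_or_non_specific")
  expect_equal(classify_lesion_outcome(
    lr(diagnosis_class = "other_cancer"))$code,
    "other_cancer_in_situ_intermediate")
  expect_equal(classify_lesion_outcome(
    lr(diagnosis_class = "other_in_situ"))$code,
    "other_cancer_in_situ_intermediate")

  expect_equal(classify_lesion_outcome(
    lr(supplemental = TRUE, peripheral_margin = "involved"))$code,
    "supplemental_peripheral_positive")
  expect_equal(classify_lesion_outcome(
    lr(supplemental = TRUE, deep_margin = "involved"))$code,
    "supplemental_deep_positive")
  expect_equal(classify_lesion_outcome(lr(supplemental = TRUE))$code,
               "supplemental_peripheral_negative")
  expect_equal(classify_lesion_outcome(
    lr(supplemental = TRUE, peripheral_margin = "not_stated",
       deep_margin = "clear"))$code, "supplemental_deep_negative")
  # peripheral involvement outranks deep involvement
  expect_equal(classify_lesion_outcome(
    lr(supplemental = TRUE, peripheral_margin = "involved",
       deep_margin = "involved"))$code, "supplemental_peripheral_positive")
})

test_that("rule order resolves overlapping conditions as fixed", {
  # other malignancy first, regardless of margins or specimen type
  expect_equal(classify_lesion_outcome(
    lr(diagnosis_class = "other_cancer", excision_type = "punch_biopsy",
       peripheral_margin = "involved"))$code,
    "other_cancer_in_situ_intermediate")
  # benign before biopsy
  expect_equal(classify_lesion_outcome(
    lr(diagnosis_class = "benign", excision_type = "punch_biopsy"))$code,
    "benign_or_non_specific")
  # diagnostic biopsy before supplemental and recurrence
  expect_equal(classify_lesion_outcome(
    lr(excision_type = "shave_biopsy", recurrent = TRUE,
       supplemental = TRUE))$code, "diagnostic_biopsy_bcc")
  # supplemental before recurrence
  expect_equal(classify_lesion_outcome(
    lr(supplemental = TRUE, recurrent = TRUE))$code,
    "supplemental_peripheral_negative")
  # recurrence before margin involvement
  expect_equal(classify_lesion_outcome(
    lr(recurrent = TRUE, deep_margin = "involved"))$code, "recurrent_bcc")
  # BCC with unknown specimen type treated as an excision
  expect_equal(classify_lesion_outcome(
    lr(excision_type = "unknown"))$code, "complete_single_bcc")
  # is_supplemental override
  expect_equal(classify_lesion_outcome(lr(), is_supplemental = TRUE)$code,
               "supplemental_peripheral_negative")
})

test_that("outcome-to-recommendation mapping matches the guideline table", {
  expected <- c(
    complete_single_bcc = "no_follow_up",
    incomplete_bcc = "re_excision",
    multiple_bccs = "follow_up_5y",
    recurrent_bcc = "follow_up_5y",
    supplemental_peripheral_positive = "re_excision",
    supplemental_peripheral_negative = "no_follow_up",
    supplemental_deep_positive = "re_excision",
    supplemental_deep_negative = "no_follow_up",
    diagnostic_biopsy_bcc = "further_surgery",
    benign_or_non_specific = "no_follow_up",
    other_cancer_in_situ_intermediate = "review")
  expect_setequal(names(outcome_codes()), names(expected))
  expect_identical(outcome_codes()[names(expected)], expected)
  for (code in names(expected)) {
    expect_identical(outcome_recommendation(code),
                     unname(expected[code]), info = code)
  }
  expect_identical(recommendation_label(unname(expected)),
                   unname(vapply(expected, recommendation_label, "")))
})

test_that("recommendation labels are the five canonical strings", {
  labs <- recommendation_classes()
  expect_length(labs, 5L)
  expect_identical(labs, sort(labs))
  expect_identical(recommendation_key(labs),
                   c("follow_up_5y", "further_surgery", "no_follow_up",
                     "re_excision", "review"))
  expect_identical(recommendation_label(recommendation_key(labs)), labs)
  expect_error(recommendation_label("nonsense"), "unknown")
})

test_that("patient aggregation applies precedence and the multiple-BCC rule", {
  d <- aggregate_recommendation(list(lr()), "P1")
  expect_equal(recommendation_key(d$recommendation), "no_follow_up")

  d <- aggregate_recommendation(list(lr("A"), lr("B")), "P1")
  codes <- vapply(d$lesion_outcomes, `[[`, "", "code")
  expect_true("multiple_bccs" %in% codes)
  expect_equal(recommendation_key(d$recommendation), "follow_up_5y")

  # one BCC plus one benign lesion is not "multiple BCCs"
  d <- aggregate_recommendation(
    list(lr("A"), lr("B", diagnosis_class = "benign")))
  expect_false("multiple_bccs" %in%
                 vapply(d$lesion_outcomes, `[[`, "", "code"))
  expect_equal(recommendation_key(d$recommendation), "no_follow_up")

  # incomplete excision outranks the multiple-BCC follow-up
  d <- aggregate_recommendation(
    list(lr("A", peripheral_margin = "involved"), lr("B")))
  expect_equal(recommendation_key(d$recommendation), "re_excision")

  # review outranks everything
  d <- aggregate_recommendation(
    list(lr("A", diagnosis_class = "other_cancer"),
         lr("B", peripheral_margin = "involved"),
         lr("C", excision_type = "punch_biopsy")))
  expect_equal(recommendation_key(d$recommendation), "review")

  # a single record may be passed bare
  d <- aggregate_recommendation(lr(recurrent = TRUE))
  expect_equal(recommendation_key(d$recommendation), "follow_up_5y")

  expect_error(aggregate_recommendation(list()), "non-empty")
})

test_that("a custom precedence reorders ties without changing outcomes", {
  recs <- list(lr("A", excision_type = "punch_biopsy"),
               lr("B", peripheral_margin = "involved"))
  default <- aggregate_recommendation(recs)
  expect_equal(recommendation_key(default$recommendation), "further_surgery")
  flipped <- aggregate_recommendation(
    recs, precedence = c("re_excision", "further_surgery", "review",
                         "follow_up_5y", "no_follow_up"))
  expect_equal(recommendation_key(flipped$recommendation), "re_excision")
  expect_identical(
    vapply(default$lesion_outcomes, `[[`, "", "code"),
    vapply(flipped$lesion_outcomes, `[[`, "", "code"))
  expect_error(aggregate_recommendation(recs, precedence = c("review")),
               "precedence")
})

test_that("single-lesion decisions agree with the enumeration oracle", {
  for (rec in decision_lattice()) {
    d <- aggregate_recommendation(list(rec))
    expect_identical(recommendation_key(d$recommendation),
                     oracle_lesion_rec(rec),
                     info = rec$specimen_label)
  }
})

test_that("the packaged fixture decisions are exactly reproduced", {
  cases <- fixture_cases()
  expect_gte(length(cases), 100L)
  for (case in cases) {
    codes <- vapply(case$records, function(r) {
      classify_lesion_outcome(r)$code
    }, character(1))
    expect_identical(unname(codes), case$expected_outcomes,
                     info = case$case_id)
    d <- aggregate_recommendation(case$records, case$case_id)
    expect_identical(d$recommendation, case$expected_recommendation,
                     info = case$case_id)
  }
})

test_that("letters substitute all placeholders and carry the decision", {
  recs <- list(lr("A", bcc_subtype = "nodular"))
  d <- aggregate_recommendation(recs, "P9")
  letter <- generate_letter(
    d, recs, patient_display_fields = list(patient_name = "A. Patient",
                                           clinician_name = "Dr B. Smith",
                                           clinic_date = "2024-01-31"))
  expect_type(letter, "character")
  expect_false(grepl("\\{[a-z_]+\\}", letter))
  expect_match(letter, "nodular", fixed = TRUE)
  expect_match(letter, d$recommendation, fixed = TRUE)
  expect_match(letter, "A. Patient", fixed = TRUE)
  # unresolved placeholders are an error, not silent output
  expect_error(generate_letter(d, recs, patient_display_fields = list()),
               "missing letter display field")
})
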