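test_that("gazetteer tagging is longest-match, sorted, evidence-faithful", {
  sp <- tag_concepts("nodular basal cell carcinoma", "diagnosis",
                     "conclusion")
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$rule_id, "dx_bcc_nodular")
  expect_equal(sp[[1]]$start, 0L)

  sp <- tag_concepts("Excision confirms BCC.", "diagnosis", "conclusion")
  expect_equal(sp[[1]]$rule_id, "dx_bcc_abbr")

  # in-situ compound suppresses the shorter invasive-cancer submatch
  sp <- tag_concepts("Squamous cell carcinoma in situ.", "diagnosis",
                     "conclusion")
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$rule_id, "dx_scc_insitu")

  expect_identical(tag_concepts("", "diagnosis"), list())
  expect_error(tag_concepts("x", "nonsense"), "unknown gazetteer_id")

  txt <- "There is a dermatofibroma and a small basal cell carcinoma."
  sps <- tag_concepts(txt, "diagnosis", "microscopic")
  starts <- vapply(sps, `[[`, 0L, "start")
  expect_identical(starts, sort(starts))
  for (sp in sps) {
    expect_identical(substr(txt, sp$start + 1L, sp$end), sp$matched_text)
  }
})

test_that("negation detection is sentence-bounded with a 6-token window", {
  check <- function(txt, expected) {
    sp <- tag_concepts(txt, "diagnosis", "microscopic")
    expect_length(sp, 1L)
    expect_identical(detect_negation(sp[[1]], txt), expected)
  }
  check("There is no evidence of basal cell carcinoma.", TRUE)
  check("Basal cell carcinoma is present.", FALSE)
  check("No inflammation but basal cell carcinoma is seen.", FALSE)
  check("Negative for melanoma.", TRUE)
  check("The specimen is free of residual basal cell carcinoma.", TRUE)
  # cue in a previous sentence does not carry over
  check("No ulceration is seen. Basal cell carcinoma is present.", FALSE)
  # more than six tokens between cue and concept
  check(paste("No features of note in the epidermis dermis or fat beyond a",
              "basal cell carcinoma."), FALSE)
})

test_that("specimen segmentation splits labelled reports and shares others", {
  r <- raw_report("R1", "P1",
    clinical_details = "Two lesions for excision.",
    macroscopic = "A. Ellipse of skin 10 x 5 mm. B. Punch biopsy of skin 4 mm.",
    microscopic = paste("A. Nodular basal cell carcinoma, completely",
                        "excised. B. Seborrhoeic keratosis."),
    conclusion = "A. Nodular BCC, completely excised. B. Seborrhoeic keratosis.")
  segs <- segment_specimens(r)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, `[[`, "", "specimen_label"), c("A", "B"))
  expect_match(segs[[1]]$sections$macroscopic, "Ellipse")
  expect_match(segs[[2]]$sections$macroscopic, "Punch")
  expect_false(grepl("Punch", segs[[1]]$sections$macroscopic))
  # unlabelled section is shared by both segments
  expect_equal(segs[[1]]$sections$clinical_details,
               segs[[2]]$sections$clinical_details)

  plain <- raw_report("R2", "P2", conclusion = "Nodular BCC.")
  segs <- segment_specimens(plain)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$specimen_label, "1")

  # empty microscopic section still yields segments from the rest
  r3 <- raw_report("R3", "P3",
    macroscopic = "A. Ellipse of skin 8 x 4 mm. B. Ellipse of skin 6 x 4 mm.",
    conclusion = "A. Dermatofibroma. B. Viral wart.")
  expect_length(segment_specimens(r3), 2L)
})

seg1 <- function(...) segment_specimens(raw_report("R", "P", ...))[[1]]

test_that("diagnosis extraction respects priority and section rank", {
  d <- extract_diagnosis(seg1(
    conclusion = "Infiltrative BCC, completely excised."))
  expect_equal(d$diagnosis_class, "bcc")
  expect_equal(d$bcc_subtype, "infiltrative")

  expect_equal(extract_diagnosis(seg1(
    conclusion = "Squamous cell carcinoma."))$diagnosis_class, "other_cancer")
  expect_equal(extract_diagnosis(seg1(
    clinical_details = "Lesion on the back."))$diagnosis_class,
    "non_specific")
  # class priority within a section: other cancer beats bcc
  expect_equal(extract_diagnosis(seg1(
    conclusion = "Melanoma with an adjacent basal cell carcinoma."
  ))$diagnosis_class, "other_cancer")
  # conclusion outranks microscopic
  expect_equal(extract_diagnosis(seg1(
    microscopic = "Sections show a dermatofibroma.",
    conclusion = "Nodular basal cell carcinoma."))$diagnosis_class, "bcc")
  # negated conclusion concept falls through to non-specific
  expect_equal(extract_diagnosis(seg1(
    conclusion = "Scar. No evidence of basal cell carcinoma."
  ))$diagnosis_class, "non_specific")
})

test_that("excision type extraction prefers the macroscopic section", {
  expect_equal(extract_excision_type(seg1(
    macroscopic = "Punch biopsy of skin 4 mm."))$excision_type,
    "punch_biopsy")
  expect_equal(extract_excision_type(seg1(
    macroscopic = "Ellipse of skin 15 x 8 mm."))$excision_type, "excision")
  expect_equal(extract_excision_type(seg1(
    conclusion = "No specimen type given."))$excision_type, "unknown")
  expect_equal(extract_excision_type(seg1(
    macroscopic = "Curettings of skin."))$excision_type, "curettage")
  # biopsy term wins over a generic excision word in the same section
  expect_equal(extract_excision_type(seg1(
    macroscopic = "Shave biopsy of the excision site."))$excision_type,
    "shave_biopsy")
})

test_that("margin extraction applies the >0/=0 rule and source priority", {
  m <- extract_margins(seg1(
    microscopic = "Nearest peripheral margin 0.5 mm, deep margin 1 mm."))
  expect_equal(m[c("peripheral_margin", "deep_margin")],
               list(peripheral_margin = "clear", deep_margin = "clear"))
  expect_equal(m$peripheral_margin_mm, 0.5)
  expect_equal(m$deep_margin_mm, 1)

  m <- extract_margins(seg1(
    microscopic = "The tumour extends to the deep margin."))
  expect_equal(m$deep_margin, "involved")
  expect_equal(m$peripheral_margin, "not_stated")
  expect_true(is.na(m$deep_margin_mm))

  m <- extract_margins(seg1(microscopic = "The deep margin 0 mm."))
  expect_equal(m$deep_margin, "involved")
  expect_equal(m$deep_margin_mm, 0)

  m <- extract_margins(seg1(
    conclusion = "BCC, incompletely excised at the peripheral margin."))
  expect_equal(m$peripheral_margin, "involved")
  expect_equal(m$deep_margin, "not_stated")

  m <- extract_margins(seg1(conclusion = "BCC; incompletely excised."))
  expect_equal(m$peripheral_margin, "involved")
  expect_equal(m$deep_margin, "involved")

  # numeric evidence outranks a conflicting lexical phrase
  m <- extract_margins(seg1(
    microscopic = "Deep margin 2 mm.",
    conclusion = "Incompletely excised at the peripheral margin."))
  expect_equal(m$deep_margin, "clear")
  expect_equal(m$peripheral_margin, "involved")

  expect_warning(
    m <- extract_margins(seg1(
      microscopic = "The deep margin 0..5 mm from tumour.")),
    "malformed")
  expect_equal(m$deep_margin, "not_stated")
})

test_that("recurrence extraction uses clinical details and negation", {
  expect_true(extract_recurrence(seg1(
    clinical_details = "Recurrent BCC left temple.",
    conclusion = "BCC."))$recurrent)
  expect_false(extract_recurrence(seg1(
    clinical_details = "No evidence of recurrence.",
    conclusion = "BCC."))$recurrent)
  expect_false(extract_recurrence(seg1(
    clinical_details = "Lesion on the nose.", conclusion = "BCC."))$recurrent)
  expect_true(extract_recurrence(seg1(
    clinical_details = "Lesion.",
    conclusion = "Recurrent nodular BCC, completely excised."))$recurrent)
})

test_that("assemble_records builds valid records and is deterministic", {
  r <- raw_report("R1", "P1",
    clinical_details = "Lesion on the left cheek.",
    macroscopic = "Ellipse of skin 12 x 7 mm.",
    microscopic = paste("Sections show a nodular basal cell carcinoma.",
                        "Nearest peripheral margin 1 mm, deep margin 2 mm."),
    conclusion = "Nodular BCC, completely excised.")
  recs <- assemble_records(r)
  expect_length(recs, 1L)
  rec <- recs[[1]]
  expect_equal(rec$diagnosis_class, "bcc")
  expect_equal(rec$excision_type, "excision")
  expect_equal(rec$peripheral_margin, "clear")
  expect_equal(rec$deep_margin, "clear")
  expect_false(rec$recurrent)
  expect_gt(length(rec$evidence), 0L)
  expect_identical(records_to_df(assemble_records(r)), records_to_df(recs))

  two <- raw_report("R2", "P2",
    macroscopic = "A. Ellipse of skin 10 x 6 mm. B. Punch biopsy of skin 4 mm.",
    conclusion = paste("A. Superficial BCC, completely excised.",
                       "B. Seborrhoeic keratosis."))
  recs <- assemble_records(two)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, "", "specimen_label"), c("A", "B"))
  expect_equal(recs[[1]]$diagnosis_class, "bcc")
  expect_equal(recs[[2]]$diagnosis_class, "benign")
  expect_equal(recs[[2]]$excision_type, "punch_biopsy")

  only_cd <- raw_report("R3", "P3",
                        clinical_details = "Lesion on the scalp.")
  recs <- assemble_records(only_cd)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$diagnosis_class, "non_specific")
  expect_equal(recs[[1]]$excision_type, "unknown")

  expect_warning(out <- assemble_records(raw_report("R4", "P4",
                                                    conclusion = " ")),
                 "no text")
  expect_length(out, 0L)
})

test_that("supplemental specimens are flagged from re-excision cues", {
  rec <- assemble_records(raw_report("R1", "P1",
    clinical_details = "Re-excision of scar on the nose.",
    macroscopic = "Ellipse of skin 14 x 6 mm.",
    conclusion = "Residual basal cell carcinoma, completely excised."))[[1]]
  expect_true(rec$supplemental)
  rec <- assemble_records(raw_report("R2", "P2",
    clinical_details = "Lesion on the nose.",
    macroscopic = "Ellipse of skin 14 x 6 mm.",
    conclusion = "BCC, completely excised."))[[1]]
  expect_false(rec$supplemental)
})

test_that("extracted records always satisfy the margin consistency law", {
  corpus <- generate_corpus(generation_config(40, seed = 77,
                                              noise_level = 0.5))
  for (rep in corpus$reports) {
    for (rec in assemble_records(rep)) {
      expect_silent(validate_lesion_record(rec))
      for (side in c("peripheral", "deep")) {
        mm <- rec[[paste0(side, "_margin_mm")]]
        st <- rec[[paste0(side, "_margin")]]
        if (!is.na(mm)) {
          expect_identical(st, if (mm > 0) "clear" else "involved")
        }
      }
      for (sp in rec$evidence) {
        sec_txt <- if (sp$section %in% names(rep$subheadings)) {
          rep$subheadings[[sp$section]]
        } else ""
        # spans are relative to the segment view, so only check shape
        expect_true(sp$start >= 0 && sp$end > sp$start)
      }
    }
  }
})
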