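## Guideline-mapped clinical decision engine: lesion-level outcome rules
## (the eleven management rows for BCC after primary surgical treatment),
## patient-level aggregation under a configurable precedence, and the
## patient letter. Output is always a hard class, never a probability.

#' Classify a lesion into one of the eleven guideline outcomes
#'
#' Rules are applied in a fixed order; the first match wins:
#' 1. diagnosis other cancer / other in situ / other intermediate ->
#'    `other_cancer_in_situ_intermediate`;
#' 2. benign or non-specific diagnosis (any margin outcome) ->
#'    `benign_or_non_specific`;
#' 3. BCC diagnosed on a sampling biopsy (punch, incision, shave,
#'    curettage) -> `diagnostic_biopsy_bcc`;
#' 4. supplementary (re-excision/cavity) specimen -> `supplemental_*` by
#'    margin polarity;
#' 5. recurrent BCC -> `recurrent_bcc`;
#' 6. any involved margin (peripheral, deep or both) -> `incomplete_bcc`;
#' 7. otherwise -> `complete_single_bcc`.
#'
#' A BCC with unknown excision type is treated as an excision
#' (conservative against over-referral to further surgery).
#'
#' @param record A [lesion_record()].
#' @param is_supplemental Treat the specimen as supplementary; defaults to
#'   the record's own `supplemental` flag.
#' @return A `lesion_outcome`: list with `code`, `triggering_rule` and
#'   `source_lesions`.
#' @export
#' @examples
#' classify_lesion_outcome(lesion_record(
#'   diagnosis_class = "bcc", excision_type = "excision",
#'   peripheral_margin = "clear", deep_margin = "clear"))$code
classify_lesion_outcome <- function(record,
                                    is_supplemental = record$supplemental) {
  validate_lesion_record(record)
  dx <- record$diagnosis_class
  any_involved <- record$peripheral_margin == "involved" ||
    record$deep_margin == "involved"
  res <- if (dx %in% c("other_cancer", "other_in_situ", "other_intermediate")) {
    c("other_cancer_in_situ_intermediate", "rule_1_other_malignancy")
  } else if (dx %in% c("benign", "non_specific")) {
    c("benign_or_non_specific", "rule_2_benign_or_non_specific")
  } else if (record$excision_type %in% .BIOPSY_TYPES) {
    c("diagnostic_biopsy_bcc", "rule_3_diagnostic_biopsy")
  } else if (isTRUE(is_supplemental)) {
    # polarity: an involved peripheral margin takes priority over deep;
    # with no involvement a clear peripheral margin reports as peripheral
    # negative, anything else as deep negative
    code <- if (record$peripheral_margin == "involved") {
      "supplemental_peripheral_positive"
    } else if (record$deep_margin == "involved") {
      "supplemental_deep_positive"
    } else if (record$peripheral_margin == "clear") {
      "supplemental_peripheral_negative"
    } else {
      "supplemental_deep_negative"
    }
    c(code, "rule_4_supplemental")
  } else if (record$recurrent) {
    c("recurrent_bcc", "rule_5_recurrent")
  } else if (any_involved) {
    c("incomplete_bcc", "rule_6_incomplete")
  } else {
    c("complete_single_bcc", "rule_7_complete")
  }
  structure(
    list(code = res[1], triggering_rule = res[2],
         source_lesions = record$specimen_label),
    class = "lesion_outcome")
}

#' @export
print.lesion_outcome <- function(x, ...) {
  cat(sprintf("<lesion_outcome> %s (%s; lesions %s) -> %s\n",
              x$code, x$triggering_rule,
              paste(x$source_lesions, collapse = ","),
              outcome_recommendation(x$code)))
  invisible(x)
}

#' Aggregate lesion records to a patient-level recommendation
#'
#' Each record is classified with [classify_lesion_outcome()]; when two or
#' more records carry a BCC diagnosis a `multiple_bccs` outcome is added
#' for the episode. The patient recommendation is the highest-precedence
#' recommendation among the mapped outcomes (default precedence: review
#' required > further excisional surgery > offer re-excision > follow-up
#' 5 years > no follow-up). The output is a hard class.
#'
#' @param records Non-empty list of [lesion_record()] objects for one
#'   decision episode.
#' @param patient_id Identifier recorded on the decision.
#' @param precedence Permutation of the five recommendation keys, highest
#'   priority first; see [default_precedence()].
#' @return A `patient_decision`: list with `patient_id`, `lesion_outcomes`,
#'   `recommendation` (canonical label) and `rationale` (fired rule ids in
#'   order).
#' @export
#' @examples
#' recs <- list(
#'   lesion_record("A", "bcc", excision_type = "excision",
#'                 peripheral_margin = "clear", deep_margin = "clear"),
#'   lesion_record("B", "bcc", excision_type = "excision",
#'                 peripheral_margin = "clear", deep_margin = "clear"))
#' aggregate_recommendation(recs)$recommendation
aggregate_recommendation <- function(records, patient_id = "unknown",
                                     precedence = default_precedence()) {
  if (!is.list(records) || length(records) == 0L ||
      inherits(records, "lesion_record")) {
    if (inherits(records, "lesion_record")) {
      records <- list(records)
    } else {
      stop("records must be a non-empty list of lesion_record objects",
           call. = FALSE)
    }
  }
  .check_precedence(precedence)
  outcomes <- lapply(records, classify_lesion_outcome)
  n_bcc <- sum(vapply(records, function(r) r$diagnosis_class == "bcc",
                      logical(1)))
  if (n_bcc >= 2L) {
    bcc_labels <- vapply(
      records[vapply(records, function(r) r$diagnosis_class == "bcc",
                     logical(1))],
      `[[`, "", "specimen_label")
    outcomes <- c(outcomes, list(structure(
      list(code = "multiple_bccs", triggering_rule = "rule_multiple_bccs",
           source_lesions = bcc_labels),
      class = "lesion_outcome")))
  }
  keys <- outcome_recommendation(vapply(outcomes, `[[`, "", "code"))
  ranks <- match(keys, precedence)
  winner <- precedence[min(ranks)]
  structure(
    list(patient_id = patient_id,
         lesion_outcomes = outcomes,
         recommendation = recommendation_label(winner),
         rationale = vapply(outcomes, `[[`, "", "triggering_rule")),
    class = "patient_decision")
}

#' @export
print.patient_decision <- function(x, ...) {
  cat("<patient_decision> ", x$patient_id, "\n", sep = "")
  for (o in x$lesion_outcomes) {
    cat("  ", o$code, " [", paste(o$source_lesions, collapse = ","), "]\n",
        sep = "")
  }
  cat("  recommendation: ", x$recommendation, "\n", sep = "")
  invisible(x)
}

.LETTER_TEMPLATE_DEFAULT <- paste(
  "Dear {patient_name},",
  "",
  "Re: histopathology results (patient ID {patient_id})",
  "",
  "Your recent skin specimen(s) showed the following:",
  "{diagnosis_lines}",
  "",
  "The recommendation of the skin multidisciplinary team is:",
  "{recommendation}",
  "",
  "Enclosed with this letter you will find a BAD patient information",
  "sheet explaining the diagnosis, as well as a Melanoma UK patient",
  "information sheet on self-examination.",
  "",
  "Yours sincerely,",
  "{clinician_name}",
  sep = "\n")

.DX_WORDING <- c(
  bcc = "basal cell carcinoma",
  benign = "a benign lesion",
  non_specific = "no specific diagnosis",
  other_cancer = "another form of skin cancer",
  other_in_situ = "an in-situ (pre-invasive) lesion",
  other_intermediate = "a lesion of intermediate malignant potential")

#' Generate the patient letter
#'
#' Renders a plain-text letter communicating each lesion's diagnosis and
#' the management recommendation verbatim, with the standard enclosures
#' (a BAD patient information sheet and a Melanoma UK patient information
#' sheet on self-examination). Rendering is deterministic and fails if a
#' required display field is missing or a placeholder is left unresolved.
#'
#' @param decision A `patient_decision` from [aggregate_recommendation()].
#' @param records The lesion records behind the decision (used for the
#'   diagnosis wording).
#' @param patient_display_fields Named list with at least `patient_name`
#'   and `clinician_name`.
#' @param template Letter template string with `{placeholder}` fields;
#'   defaults to the packaged template.
#' @return The letter text (single string).
#' @export
generate_letter <- function(decision, records, patient_display_fields,
                            template = .LETTER_TEMPLATE_DEFAULT) {
  stopifnot(inherits(decision, "patient_decision"))
  dx_lines <- vapply(records, function(r) {
    wording <- .DX_WORDING[[r$diagnosis_class]]
    if (r$diagnosis_class == "bcc" && !is.na(r$bcc_subtype)) {
      wording <- paste0(wording, " (", r$bcc_subtype, " type)")
    }
    paste0("  - specimen ", r$specimen_label, ": ", wording)
  }, character(1))
  fields <- c(
    patient_display_fields,
    list(patient_id = decision$patient_id,
         diagnosis_lines = paste(dx_lines, collapse = "\n"),
         recommendation = decision$recommendation))
  out <- template
  for (nm in names(fields)) {
    out <- gsub(paste0("{", nm, "}"), fields[[nm]], out, fixed = TRUE)
  }
  leftover <- regmatches(out, gregexpr("\\{[a-z_]+\\}", out))[[1]]
  if (length(leftover) > 0L) {
    stop("missing letter display field(s): ",
         paste(gsub("[{}]", "", leftover), collapse = ", "), call. = FALSE)
  }
  out
}
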