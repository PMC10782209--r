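#' @importFrom stringi stri_trans_nfkc
NULL

.SECTION_NAMES <- c("clinical_details", "macroscopic", "microscopic", "conclusion")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct a raw histopathology report
#'
#' A report is a set of texts under the canonical subheadings of a
#' histopathology report: clinical details, macroscopic description,
#' microscopic description and conclusion. Texts are Unicode
#' NFKC-normalised on construction; all evidence offsets refer to the
#' stored (normalised) section texts.
#'
#' @param report_id,patient_id Identifiers (non-empty strings).
#' @param clinical_details,macroscopic,microscopic,conclusion Section texts
#'   (single strings; may be empty, but not all of them).
#' @return An object of class `raw_report` with fields `report_id`,
#'   `patient_id`, `subheadings` (named list in canonical order) and
#'   `raw_text` (concatenation of the subheadings in canonical order).
#' @export
#' @examples
#' r <- raw_report("R1", "P1",
#'   clinical_details = "Lesion left temple.",
#'   macroscopic = "Ellipse of skin 12 x 6 mm.",
#'   microscopic = "Nodular basal cell carcinoma, completely excised.",
#'   conclusion = "Nodular BCC, completely excised.")
#' r
raw_report <- function(report_id, patient_id,
                       clinical_details = "", macroscopic = "",
                       microscopic = "", conclusion = "") {
  stopifnot(is.character(report_id), length(report_id) == 1L, nzchar(report_id),
            is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  sections <- lapply(
    list(clinical_details = clinical_details, macroscopic = macroscopic,
         microscopic = microscopic, conclusion = conclusion),
    function(x) {
      stopifnot(is.character(x), length(x) == 1L)
      stringi::stri_trans_nfkc(x)
    })
  if (!any(nzchar(unlist(sections)))) {
    stop("a report needs at least one non-empty subheading", call. = FALSE)
  }
  structure(
    list(report_id = report_id, patient_id = patient_id,
         subheadings = sections,
         raw_text = paste(unlist(sections), collapse = "\n")),
    class = "raw_report")
}

#' @export
print.raw_report <- function(x, ...) {
  cat("<raw_report> ", x$report_id, " (patient ", x$patient_id, ")\n", sep = "")
  for (s in .SECTION_NAMES) {
    txt <- x$subheadings[[s]]
    if (nzchar(txt)) {
      cat("  ", s, ": ", substr(txt, 1, 68),
          if (nchar(txt) > 68) "..." else "", "\n", sep = "")
    }
  }
  invisible(x)
}

#' Construct an evidence span
#'
#' A span of section text supporting an extracted field value. Offsets are
#' 0-based, end-exclusive, relative to the (NFKC-normalised) section text.
#'
#' @param section Section name.
#' @param start,end Integer offsets, `0 <= start < end`.
#' @param matched_text The exact text at `[start, end)`.
#' @param rule_id Identifier of the gazetteer entry or rule that matched.
#' @return An object of class `evidence_span`.
#' @export
evidence_span <- function(section, start, end, matched_text, rule_id) {
  stopifnot(section %in% .SECTION_NAMES,
            is.numeric(start), is.numeric(end),
            start >= 0, start < end,
            is.character(matched_text), length(matched_text) == 1L,
            is.character(rule_id), length(rule_id) == 1L)
  structure(
    list(section = section, start = as.integer(start), end = as.integer(end),
         matched_text = matched_text, rule_id = rule_id),
    class = "evidence_span")
}

#' @export
print.evidence_span <- function(x, ...) {
  cat(sprintf("<evidence_span> %s[%d,%d) %s \"%s\"\n",
              x$section, x$start, x$end, x$rule_id, x$matched_text))
  invisible(x)
}

#' Construct a structured lesion record
#'
#' The structured extraction for one specimen/lesion. Margin semantics
#' follow histopathological reporting standards for primary BCC: a margin
#' is clear if its nearest distance exceeds 0 mm and involved if 0 mm, so a
#' stated distance of 0 forces status `involved` and a positive distance
#' forces `clear` (enforced here).
#'
#' @param specimen_label Specimen label within the report ("A", "B", or "1"
#'   when unlabelled).
#' @param diagnosis_class One of `"bcc"`, `"benign"`, `"non_specific"`,
#'   `"other_cancer"`, `"other_in_situ"`, `"other_intermediate"`.
#' @param bcc_subtype Optional growth-pattern subtype (only when
#'   `diagnosis_class == "bcc"`).
#' @param excision_type One of `"punch_biopsy"`, `"incision_biopsy"`,
#'   `"shave_biopsy"`, `"curettage"`, `"excision"`, `"unknown"`.
#' @param peripheral_margin,deep_margin `"clear"`, `"involved"` or
#'   `"not_stated"`.
#' @param peripheral_margin_mm,deep_margin_mm Optional nearest margin
#'   distances in millimetres (non-negative).
#' @param recurrent Logical: recurrent (vs primary) lesion.
#' @param supplemental Logical: supplementary (re-excision/cavity) specimen
#'   of a previously treated lesion.
#' @param evidence List of [evidence_span()] objects supporting the
#'   non-default field values.
#' @return An object of class `lesion_record`.
#' @export
lesion_record <- function(specimen_label = "1",
                          diagnosis_class = "non_specific",
                          bcc_subtype = NA_character_,
                          excision_type = "unknown",
                          peripheral_margin = "not_stated",
                          deep_margin = "not_stated",
                          peripheral_margin_mm = NA_real_,
                          deep_margin_mm = NA_real_,
                          recurrent = FALSE,
                          supplemental = FALSE,
                          evidence = list()) {
  rec <- structure(
    list(specimen_label = as.character(specimen_label),
         diagnosis_class = diagnosis_class,
         bcc_subtype = as.character(bcc_subtype),
         excision_type = excision_type,
         peripheral_margin = peripheral_margin,
         deep_margin = deep_margin,
         peripheral_margin_mm = as.numeric(peripheral_margin_mm),
         deep_margin_mm = as.numeric(deep_margin_mm),
         recurrent = isTRUE(recurrent),
         supplemental = isTRUE(supplemental),
         evidence = evidence),
    class = "lesion_record")
  validate_lesion_record(rec)
}

#' Validate a lesion record
#'
#' Checks field domains and the margin consistency law
#' (`margin_mm == 0` iff status `involved`; `margin_mm > 0` implies
#' status `clear`), and that subtypes only accompany a BCC diagnosis.
#'
#' @param rec A `lesion_record`.
#' @return The record, invisibly unchanged, or an error.
#' @export
validate_lesion_record <- function(rec) {
  stopifnot(inherits(rec, "lesion_record"))
  if (!rec$diagnosis_class %in% .DIAGNOSIS_CLASSES) {
    stop("invalid diagnosis_class: ", rec$diagnosis_class, call. = FALSE)
  }
  if (!rec$excision_type %in% .EXCISION_TYPES) {
    stop("invalid excision_type: ", rec$excision_type, call. = FALSE)
  }
  for (side in c("peripheral", "deep")) {
    status <- rec[[paste0(side, "_margin")]]
    mm <- rec[[paste0(side, "_margin_mm")]]
    if (!status %in% .MARGIN_STATUSES) {
      stop("invalid ", side, "_margin status: ", status, call. = FALSE)
    }
    if (!is.na(mm)) {
      if (mm < 0) stop(side, "_margin_mm must be non-negative", call. = FALSE)
      if (mm == 0 && status != "involved") {
        stop(side, " margin 0 mm must have status 'involved'", call. = FALSE)
      }
      if (mm > 0 && status != "clear") {
        stop(side, " margin > 0 mm must have status 'clear'", call. = FALSE)
      }
    }
    # involved without a stated distance is allowed (lexical evidence only)
  }
  if (rec$diagnosis_class != "bcc" && !is.na(rec$bcc_subtype)) {
    stop("bcc_subtype requires diagnosis_class 'bcc'", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf(
    "<lesion_record> %s: %s%s, %s, margins P=%s%s D=%s%s%s%s (%d evidence spans)\n",
    x$specimen_label, x$diagnosis_class,
    if (!is.na(x$bcc_subtype)) paste0("/", x$bcc_subtype) else "",
    x$excision_type,
    x$peripheral_margin,
    if (!is.na(x$peripheral_margin_mm)) sprintf(" (%g mm)", x$peripheral_margin_mm) else "",
    x$deep_margin,
    if (!is.na(x$deep_margin_mm)) sprintf(" (%g mm)", x$deep_margin_mm) else "",
    if (x$recurrent) ", recurrent" else "",
    if (x$supplemental) ", supplemental" else "",
    length(x$evidence)))
  invisible(x)
}

#' Convert lesion records to a data frame
#'
#' One row per record, columns in `lesion_record` field order (evidence
#' spans are not included; [write_extractions()] serialises them
#' separately as JSON lines).
#'
#' @param records List of `lesion_record` objects.
#' @param patient_id,report_id Optional identifier columns to prepend
#'   (recycled).
#' @return A data frame.
#' @export
records_to_df <- function(records, patient_id = NULL, report_id = NULL) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      specimen_label = r$specimen_label,
      diagnosis_class = r$diagnosis_class,
      bcc_subtype = r$bcc_subtype,
      excision_type = r$excision_type,
      peripheral_margin = r$peripheral_margin,
      deep_margin = r$deep_margin,
      peripheral_margin_mm = r$peripheral_margin_mm,
      deep_margin_mm = r$deep_margin_mm,
      recurrent = r$recurrent,
      supplemental = r$supplemental,
      stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(
      specimen_label = character(), diagnosis_class = character(),
      bcc_subtype = character(), excision_type = character(),
      peripheral_margin = character(), deep_margin = character(),
      peripheral_margin_mm = numeric(), deep_margin_mm = numeric(),
      recurrent = logical(), supplemental = logical(),
      stringsAsFactors = FALSE)
  }
  if (!is.null(patient_id)) df <- cbind(patient_id = patient_id, df)
  if (!is.null(report_id)) {
    df <- cbind(df[, "patient_id", drop = FALSE], report_id = report_id,
                df[, setdiff(names(df), "patient_id"), drop = FALSE])
  }
  df
}

#' Rebuild lesion records from a data frame
#'
#' Inverse of [records_to_df()] (evidence is not round-tripped).
#'
#' @param df A data frame with the `records_to_df()` columns.
#' @return List of `lesion_record` objects.
#' @export
df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    lesion_record(
      specimen_label = df$specimen_label[i],
      diagnosis_class = df$diagnosis_class[i],
      bcc_subtype = if ("bcc_subtype" %in% names(df)) df$bcc_subtype[i] else NA,
      excision_type = df$excision_type[i],
      peripheral_margin = df$peripheral_margin[i],
      deep_margin = df$deep_margin[i],
      peripheral_margin_mm =
        if ("peripheral_margin_mm" %in% names(df)) df$peripheral_margin_mm[i] else NA,
      deep_margin_mm =
        if ("deep_margin_mm" %in% names(df)) df$deep_margin_mm[i] else NA,
      recurrent = isTRUE(as.logical(df$recurrent[i])),
      supplemental = if ("supplemental" %in% names(df))
        isTRUE(as.logical(df$supplemental[i])) else FALSE)
  })
}
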