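#' Recommendation classes and outcome codes
#'
#' The decision engine works internally with short keys; all user-facing
#' output (decisions CSV, letters, confusion matrices) uses the full
#' recommendation wording from the national BCC management guidance.
#' The wording is canonical: confusion-matrix row/column labels depend on
#' byte-identical strings.
#'
#' @name recommendation-classes
NULL

# short key -> canonical label, in lexicographic label order
.REC_LABELS <- c(
  follow_up_5y    = "Follow-up 6-monthly for 5 years",
  further_surgery = paste(
    "Further excisional surgery, destructive surgical or non-surgical",
    "technique recommended to obtain oncological clearance"),
  no_follow_up    = "No follow-up",
  re_excision     = "Offer re-excision. If declined follow-up 6-monthly for 2 years",
  review          = paste(
    "Other cancerous, in situ or intermediate lesion. Review of",
    "histopathology free text required to guide management")
)

# lesion outcome code -> recommendation key (the eleven guideline rows)
.OUTCOME_TO_REC <- c(
  complete_single_bcc               = "no_follow_up",
  incomplete_bcc                    = "re_excision",
  multiple_bccs                     = "follow_up_5y",
  recurrent_bcc                     = "follow_up_5y",
  supplemental_peripheral_positive  = "re_excision",
  supplemental_peripheral_negative  = "no_follow_up",
  supplemental_deep_positive        = "re_excision",
  supplemental_deep_negative        = "no_follow_up",
  diagnostic_biopsy_bcc             = "further_surgery",
  benign_or_non_specific            = "no_follow_up",
  other_cancer_in_situ_intermediate = "review"
)

# default precedence, highest priority first: escalating intervention,
# review-required on top because it demands human attention
.DEFAULT_PRECEDENCE <- c(
  "review", "further_surgery", "re_excision", "follow_up_5y", "no_follow_up"
)

.DIAGNOSIS_CLASSES <- c(
  "bcc", "benign", "non_specific",
  "other_cancer", "other_in_situ", "other_intermediate"
)

.EXCISION_TYPES <- c(
  "punch_biopsy", "incision_biopsy", "shave_biopsy", "curettage",
  "excision", "unknown"
)

.BIOPSY_TYPES <- c("punch_biopsy", "incision_biopsy", "shave_biopsy", "curettage")

.MARGIN_STATUSES <- c("clear", "involved", "not_stated")

#' Canonical recommendation class labels
#'
#' Returns the five patient-level recommendation labels in their canonical
#' (lexicographic) order, the order used for confusion-matrix rows and
#' columns.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' recommendation_classes()
recommendation_classes <- function() {
  unname(.REC_LABELS[order(.REC_LABELS)])
}

#' Map recommendation keys to canonical labels (and back)
#'
#' @param key Character vector of short keys (`"no_follow_up"`,
#'   `"follow_up_5y"`, `"re_excision"`, `"further_surgery"`, `"review"`).
#' @return `recommendation_label()`: the canonical label(s);
#'   `recommendation_key()`: the short key(s).
#' @export
recommendation_label <- function(key) {
  bad <- setdiff(key, names(.REC_LABELS))
  if (length(bad) > 0L) {
    stop("unknown recommendation key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(.REC_LABELS[key])
}

#' @rdname recommendation_label
#' @param label Character vector of canonical labels.
#' @export
recommendation_key <- function(label) {
  idx <- match(label, .REC_LABELS)
  if (anyNA(idx)) {
    stop("unknown recommendation label: ",
         paste(label[is.na(idx)], collapse = "; "), call. = FALSE)
  }
  names(.REC_LABELS)[idx]
}

#' Lesion outcome codes
#'
#' The eleven histopathology-report outcomes the decision engine can assign
#' to a lesion (or, for `multiple_bccs`, to a patient episode), each mapping
#' to exactly one recommendation class.
#'
#' @return Named character vector: outcome code -> recommendation key.
#' @export
outcome_codes <- function() .OUTCOME_TO_REC

#' Recommendation for a lesion outcome code
#'
#' @param code Character vector of outcome codes.
#' @param as_label Return canonical labels rather than short keys.
#' @return Character vector of recommendation keys or labels.
#' @export
outcome_recommendation <- function(code, as_label = FALSE) {
  bad <- setdiff(code, names(.OUTCOME_TO_REC))
  if (length(bad) > 0L) {
    stop("unknown outcome code: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- unname(.OUTCOME_TO_REC[code])
  if (as_label) recommendation_label(key) else key
}

#' Default recommendation precedence
#'
#' Order in which conflicting lesion-level recommendations are resolved to a
#' single patient-level recommendation; first element wins.
#'
#' @return Character vector of the five recommendation keys, highest
#'   priority first.
#' @export
default_precedence <- function() .DEFAULT_PRECEDENCE

.check_precedence <- function(precedence) {
  if (!is.character(precedence) ||
      !setequal(precedence, .DEFAULT_PRECEDENCE) ||
      anyDuplicated(precedence)) {
    stop("precedence must be a permutation of: ",
         paste(.DEFAULT_PRECEDENCE, collapse = ", "), call. = FALSE)
  }
  precedence
}
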