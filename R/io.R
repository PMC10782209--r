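## Readers and writers: corpus artefacts (per-report text files, corpus
## and gold-label CSVs, JSON manifest), extraction and decision CSVs,
## evidence JSON-lines, the packaged confusion-matrix fixture, and the
## structured decision-case fixture. All CSVs are RFC 4180 with a header
## row, UTF-8.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a corpus to disk
#'
#' Writes one UTF-8 text file per report (`<patient_id>_<report_id>.txt`,
#' sections under upper-case headings), a corpus CSV (one row per report:
#' `patient_id`, `report_id`, then the four subheadings), a gold-label CSV
#' (one row per lesion plus the expected outcome and recommendation) and
#' the JSON manifest.
#'
#' @param corpus A `smdt_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "smdt_corpus"))
  dir.create(file.path(dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  for (rep in corpus$reports) {
    lines <- unlist(lapply(.SECTION_NAMES, function(sec) {
      c(paste0(toupper(gsub("_", " ", sec)), ":"),
        rep$subheadings[[sec]], "")
    }))
    writeLines(lines, file.path(dir, "reports",
                                paste0(rep$patient_id, "_",
                                       rep$report_id, ".txt")),
               useBytes = TRUE)
  }
  corpus_df <- do.call(rbind, lapply(corpus$reports, function(r) {
    data.frame(patient_id = r$patient_id, report_id = r$report_id,
               clinical_details = r$subheadings$clinical_details,
               macroscopic = r$subheadings$macroscopic,
               microscopic = r$subheadings$microscopic,
               conclusion = r$subheadings$conclusion,
               stringsAsFactors = FALSE)
  }))
  .write_csv(corpus_df, file.path(dir, "corpus.csv"))
  gold_df <- do.call(rbind, lapply(corpus$gold, function(g) {
    df <- records_to_df(g$lesions, patient_id = g$patient_id)
    df$expected_recommendation <- g$expected_recommendation
    df$expected_lesion_outcomes <- paste(g$expected_lesion_outcomes,
                                         collapse = ";")
    df
  }))
  .write_csv(gold_df, file.path(dir, "gold_labels.csv"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus back from disk
#'
#' Inverse of [write_corpus()] (reports and gold labels; the per-lesion
#' evidence of gold records is not stored).
#'
#' @param dir Directory written by [write_corpus()].
#' @return A `smdt_corpus`.
#' @export
read_corpus <- function(dir) {
  corpus_df <- .read_csv(file.path(dir, "corpus.csv"))
  reports <- lapply(seq_len(nrow(corpus_df)), function(i) {
    raw_report(corpus_df$report_id[i], corpus_df$patient_id[i],
               clinical_details = corpus_df$clinical_details[i],
               macroscopic = corpus_df$macroscopic[i],
               microscopic = corpus_df$microscopic[i],
               conclusion = corpus_df$conclusion[i])
  })
  gold_df <- .read_csv(file.path(dir, "gold_labels.csv"))
  gold <- lapply(split(gold_df, gold_df$patient_id), function(g) {
    structure(
      list(patient_id = g$patient_id[1],
           lesions = df_to_records(g),
           expected_lesion_outcomes =
             strsplit(g$expected_lesion_outcomes[1], ";", fixed = TRUE)[[1]],
           expected_recommendation = g$expected_recommendation[1]),
      class = "gold_case")
  })
  gold <- gold[order(names(gold))]
  names(gold) <- NULL
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(reports = reports, gold = gold, manifest = manifest),
            class = "smdt_corpus")
}

#' Write extraction results
#'
#' One CSV row per lesion record (field order as in [lesion_record()]) and
#' one JSON line per evidence span.
#'
#' @param extractions Named list: per report, the list of lesion records
#'   (names are patient ids).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_extractions <- function(extractions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- do.call(rbind, lapply(names(extractions), function(pid) {
    records_to_df(extractions[[pid]], patient_id = pid)
  }))
  .write_csv(df, file.path(dir, "extractions.csv"))
  con <- file(file.path(dir, "evidence.jsonl"), open = "w",
              encoding = "UTF-8")
  on.exit(close(con))
  for (pid in names(extractions)) {
    for (rec in extractions[[pid]]) {
      for (sp in rec$evidence) {
        writeLines(jsonlite::toJSON(
          c(list(patient_id = pid,
                 specimen_label = rec$specimen_label), unclass(sp)),
          auto_unbox = TRUE), con)
      }
    }
  }
  invisible(dir)
}

#' Read extraction results
#'
#' @param path Path to an `extractions.csv` written by
#'   [write_extractions()].
#' @return Named list of lesion-record lists, one element per patient.
#' @export
read_extractions <- function(path) {
  df <- .read_csv(path)
  out <- lapply(split(df, df$patient_id), df_to_records)
  out[order(names(out))]
}

#' Write patient decisions
#'
#' @param decisions List of `patient_decision` objects.
#' @param path Output CSV path (`patient_id`, `recommendation`,
#'   semicolon-joined rule ids).
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  df <- do.call(rbind, lapply(decisions, function(d) {
    data.frame(patient_id = d$patient_id,
               recommendation = d$recommendation,
               rules = paste(d$rationale, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  .write_csv(df, path)
  invisible(path)
}

#' Write a confusion matrix as CSV
#'
#' Reference classes as columns, prediction classes as rows (first
#' column `prediction` holds the row labels).
#'
#' @param cm A `confusion_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix_csv <- function(cm, path) {
  df <- data.frame(prediction = cm$class_labels, cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("prediction", cm$class_labels)
  .write_csv(df, path)
  invisible(path)
}

#' Read a confusion matrix from CSV
#'
#' @param path CSV written by [write_confusion_matrix_csv()] (first column
#'   row labels, remaining columns reference classes).
#' @return A `confusion_matrix`.
#' @export
read_confusion_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  counts <- as.matrix(df[, -1, drop = FALSE])
  new_confusion_matrix(counts, df[[1]])
}

#' The packaged validation confusion matrix
#'
#' The 5x5 reference-versus-prediction matrix of the clinical validation
#' study (1045 lesion episodes; rows = system prediction, columns =
#' expert-clinician reference), shipped as
#' `extdata/table2_confusion_matrix.csv`.
#'
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' cm <- validation_confusion_matrix()
#' sum(cm$counts)
validation_confusion_matrix <- function() {
  read_confusion_matrix_csv(system.file(
    "extdata", "table2_confusion_matrix.csv", package = "skinmdt"))
}

#' The packaged structured decision-case fixture
#'
#' Structured lesion cases covering every row of the guideline rule table,
#' with hand-assigned expected lesion outcomes and patient-level
#' recommendations, mirroring the training check used when the decision
#' engine of the original system was built.
#'
#' @return Data frame, one row per lesion: case id, lesion attributes,
#'   `expected_outcome` and `expected_recommendation` (canonical label).
#' @export
decision_case_fixture <- function() {
  df <- .read_csv(system.file("extdata", "decision_cases.csv",
                              package = "skinmdt"))
  df$expected_recommendation <-
    recommendation_label(df$expected_recommendation_key)
  df
}

#' Expand a confusion matrix into label pairs
#'
#' Replays each cell count as that many (reference, prediction) pairs, so
#' pair-level operations can be validated against printed cell counts.
#'
#' @param cm A `confusion_matrix`.
#' @return Data frame with columns `reference` and `prediction`.
#' @export
confusion_matrix_to_pairs <- function(cm) {
  idx <- which(cm$counts > 0, arr.ind = TRUE)
  ref <- character(0); pred <- character(0)
  for (k in seq_len(nrow(idx))) {
    n <- cm$counts[idx[k, 1], idx[k, 2]]
    pred <- c(pred, rep(cm$class_labels[idx[k, 1]], n))
    ref <- c(ref, rep(cm$class_labels[idx[k, 2]], n))
  }
  data.frame(reference = ref, prediction = pred, stringsAsFactors = FALSE)
}

#' Filter a coded cohort for surgically managed BCC
#'
#' Retains records carrying at least one diagnosis code from
#' `bcc_code_set` and, when `surgical_only`, management `"surgery"`.
#' Input order is preserved. Codes are simulated SNOMED-style strings.
#'
#' @param records Data frame with columns `patient_id`, `report_id`,
#'   `coded_diagnoses` (semicolon-separated code strings) and
#'   `management` (`"surgery"` or `"non_surgical"`).
#' @param bcc_code_set Non-empty character vector of qualifying codes.
#' @param surgical_only Restrict to surgically managed patients.
#' @return The filtered data frame.
#' @export
filter_cohort <- function(records, bcc_code_set, surgical_only = TRUE) {
  if (length(bcc_code_set) == 0L) {
    stop("bcc_code_set must be non-empty", call. = FALSE)
  }
  stopifnot(all(c("patient_id", "report_id", "coded_diagnoses",
                  "management") %in% names(records)))
  has_code <- vapply(strsplit(records$coded_diagnoses, ";", fixed = TRUE),
                     function(cs) any(trimws(cs) %in% bcc_code_set),
                     logical(1))
  keep <- has_code
  if (surgical_only) keep <- keep & records$management == "surgery"
  records[keep, , drop = FALSE]
}
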