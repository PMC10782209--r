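## Rule-based information extraction: gazetteer tagging, negation handling,
## specimen segmentation and field extractors. A deliberately small,
## transparent rule set: every extracted value carries evidence spans, and
## rules live in editable CSV gazetteers under extdata/gazetteers.

.gazetteer_cache <- new.env(parent = emptyenv())

.GAZETTEER_IDS <- c("diagnosis", "excision_type", "margin", "recurrence",
                    "negation_cues")

#' Load a gazetteer
#'
#' Gazetteers are CSV files with columns `term`, `rule_id`, `attribute`,
#' `value`. The packaged set lives under `extdata/gazetteers`; a directory
#' of replacement CSVs can be supplied to customise the rules.
#'
#' @param gazetteer_id One of `"diagnosis"`, `"excision_type"`, `"margin"`,
#'   `"recurrence"`, `"negation_cues"`.
#' @param dir Optional directory containing `<gazetteer_id>.csv`; defaults
#'   to the packaged gazetteers.
#' @return A data frame with the four gazetteer columns.
#' @export
load_gazetteer <- function(gazetteer_id, dir = NULL) {
  if (!gazetteer_id %in% .GAZETTEER_IDS) {
    stop("unknown gazetteer_id: ", gazetteer_id, " (expected one of ",
         paste(.GAZETTEER_IDS, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(dir)) {
    key <- gazetteer_id
    if (!is.null(.gazetteer_cache[[key]])) return(.gazetteer_cache[[key]])
    path <- system.file("extdata", "gazetteers",
                        paste0(gazetteer_id, ".csv"), package = "skinmdt")
    gaz <- utils::read.csv(path, stringsAsFactors = FALSE)
    .gazetteer_cache[[key]] <- gaz
    return(gaz)
  }
  utils::read.csv(file.path(dir, paste0(gazetteer_id, ".csv")),
                  stringsAsFactors = FALSE)
}

.nfkc <- function(x) stringi::stri_trans_nfkc(x)

#' Tag gazetteer concepts in text
#'
#' Case-insensitive matching of gazetteer terms at word boundaries, after
#' Unicode NFKC normalisation. When matches overlap the longest wins (ties
#' broken by earlier start); surviving spans are returned sorted by start
#' offset. Offsets are 0-based, end-exclusive.
#'
#' @param text A single string.
#' @param gazetteer_id Gazetteer to use (see [load_gazetteer()]).
#' @param section Section name recorded on the returned spans.
#' @return List of [evidence_span()] objects.
#' @export
#' @examples
#' sp <- tag_concepts("Nodular basal cell carcinoma.", "diagnosis",
#'                    "conclusion")
#' sp[[1]]$rule_id
tag_concepts <- function(text, gazetteer_id, section = "microscopic") {
  gaz <- load_gazetteer(gazetteer_id)
  txt <- .nfkc(text)
  if (!nzchar(txt)) return(list())
  starts <- integer(0); lens <- integer(0); rules <- character(0)
  for (i in seq_len(nrow(gaz))) {
    pat <- paste0("(?<![A-Za-z0-9])\\Q", gaz$term[i], "\\E(?![A-Za-z0-9])")
    m <- gregexpr(pat, txt, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- c(starts, as.integer(m))
    lens <- c(lens, attr(m, "match.length"))
    rules <- c(rules, rep(gaz$rule_id[i], length(m)))
  }
  if (length(starts) == 0L) return(list())
  # longest-match-wins overlap suppression
  ord <- order(-lens, starts)
  keep <- logical(length(starts))
  taken_s <- integer(0); taken_e <- integer(0)
  for (k in ord) {
    s <- starts[k]; e <- starts[k] + lens[k]
    if (!any(taken_s < e & taken_e > s)) {
      keep[k] <- TRUE
      taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
    }
  }
  idx <- which(keep)[order(starts[keep])]
  lapply(idx, function(k) {
    evidence_span(section, starts[k] - 1L, starts[k] - 1L + lens[k],
                  substr(txt, starts[k], starts[k] + lens[k] - 1L), rules[k])
  })
}

.gaz_value <- function(gazetteer_id, rule_id) {
  gaz <- load_gazetteer(gazetteer_id)
  gaz$value[match(rule_id, gaz$rule_id)]
}

# sentence containing 0-based offset `pos`: 1-based [start, end] char range
.sentence_bounds <- function(text, pos) {
  br <- gregexpr("[.!?;]", text)[[1]]
  br <- br[br > 0]
  s <- if (any(br <= pos)) max(br[br <= pos]) + 1L else 1L
  e <- if (any(br > pos)) min(br[br > pos]) else nchar(text)
  c(s, e)
}

#' Detect negation of a concept span
#'
#' NegEx-style pre-negation: a span counts as negated when a negation cue
#' occurs in the same sentence, at most 6 tokens before the span, with the
#' scope terminated by an intervening "but" or "however" or by the
#' sentence boundary.
#'
#' @param span An [evidence_span()].
#' @param section_text The (NFKC-normalised) text the span's offsets refer
#'   to.
#' @return `TRUE` if the span is negated.
#' @export
#' @examples
#' txt <- "There is no evidence of basal cell carcinoma."
#' sp <- tag_concepts(txt, "diagnosis", "conclusion")[[1]]
#' detect_negation(sp, txt)
detect_negation <- function(span, section_text) {
  txt <- .nfkc(section_text)
  if (span$end > nchar(txt)) stop("span exceeds section text", call. = FALSE)
  sb <- .sentence_bounds(txt, span$start)
  if (sb[1] > span$start) return(FALSE)   # span starts a sentence
  prefix <- substr(txt, sb[1], span$start)  # text strictly before the span
  cues <- load_gazetteer("negation_cues")
  last_end <- -1L
  for (term in cues$term) {
    pat <- paste0("(?<![A-Za-z0-9])\\Q", term, "\\E(?![A-Za-z0-9])")
    m <- gregexpr(pat, prefix, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    last_end <- max(last_end, max(ends))
  }
  if (last_end < 0L) return(FALSE)
  between <- substr(prefix, last_end + 1L, nchar(prefix))
  toks <- strsplit(trimws(between), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  clean <- tolower(gsub("[^a-z]", "", tolower(toks)))
  if (any(clean %in% c("but", "however"))) return(FALSE)
  length(toks) <= 6L
}

#' Split a report into specimen segments
#'
#' Reports covering several specimens label them "A.", "Specimen B:",
#' "1)" and so on. Each section's text is partitioned at those markers;
#' sections carrying no marker are shared unchanged by every segment.
#' A report with no markers anywhere yields a single segment labelled
#' `"1"`.
#'
#' @param report A [raw_report()].
#' @return List of segments, each a list with `specimen_label` and
#'   `sections` (named list of per-section text views).
#' @export
segment_specimens <- function(report) {
  stopifnot(inherits(report, "raw_report"))
  marker_pat <- "(^|[.!?]\\s+)(Specimen\\s+)?([A-H]|[1-9])[.):]\\s+(?=[A-Z])"
  found <- list()  # per section: data.frame(label, cut)
  for (sec in .SECTION_NAMES) {
    txt <- report$subheadings[[sec]]
    if (!nzchar(txt)) next
    m <- gregexpr(marker_pat, txt, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    labels <- substring(txt, cs[, 3], cs[, 3] + cl[, 3] - 1L)
    # segment begins at "Specimen"/label, after any sentence-end prefix
    cuts <- ifelse(cl[, 2] > 0, cs[, 2], cs[, 3])
    found[[sec]] <- data.frame(label = labels, cut = cuts,
                               stringsAsFactors = FALSE)
  }
  all_labels <- unique(unlist(lapply(found, `[[`, "label")))
  if (length(all_labels) == 0L) all_labels <- "1"
  lapply(all_labels, function(lab) {
    sections <- lapply(.SECTION_NAMES, function(sec) {
      txt <- report$subheadings[[sec]]
      f <- found[[sec]]
      if (is.null(f)) return(txt)          # unsegmented: shared view
      i <- match(lab, f$label)
      if (is.na(i)) return("")
      from <- f$cut[i]
      to <- if (i < nrow(f)) f$cut[i + 1L] - 1L else nchar(txt)
      trimws(substr(txt, from, to))
    })
    names(sections) <- .SECTION_NAMES
    list(specimen_label = lab, sections = sections)
  })
}

.DX_PRIORITY <- c(other_cancer = 1, bcc = 2, other_in_situ = 3,
                  other_intermediate = 4, benign = 5)

#' Extract the diagnosis for one specimen segment
#'
#' Non-negated diagnosis concepts are resolved with priority
#' other cancer > BCC > other in situ > other intermediate > benign; the
#' conclusion outranks the microscopic description when they disagree.
#' With no concept anywhere the diagnosis is `non_specific`.
#'
#' @param segment One element of [segment_specimens()] output.
#' @return List with `diagnosis_class`, `bcc_subtype` and `evidence`.
#' @export
extract_diagnosis <- function(segment) {
  for (sec in c("conclusion", "microscopic")) {
    txt <- segment$sections[[sec]]
    if (!nzchar(txt)) next
    spans <- tag_concepts(txt, "diagnosis", section = sec)
    if (length(spans) == 0L) next
    neg <- vapply(spans, detect_negation, logical(1), section_text = txt)
    spans <- spans[!neg]
    if (length(spans) == 0L) next
    vals <- .gaz_value("diagnosis", vapply(spans, `[[`, "", "rule_id"))
    cls <- vapply(strsplit(vals, "/", fixed = TRUE), `[[`, "", 1L)
    best <- cls[which.min(.DX_PRIORITY[cls])]
    sel <- cls == best
    subtype <- NA_character_
    if (best == "bcc") {
      with_sub <- vals[sel][grepl("/", vals[sel], fixed = TRUE)]
      if (length(with_sub) > 0L) {
        subtype <- strsplit(with_sub[1L], "/", fixed = TRUE)[[1L]][2L]
      }
    }
    return(list(diagnosis_class = best, bcc_subtype = subtype,
                evidence = spans[sel]))
  }
  list(diagnosis_class = "non_specific", bcc_subtype = NA_character_,
       evidence = list())
}

#' Extract the specimen/excision type
#'
#' The macroscopic description is preferred (it names the specimen);
#' microscopic and conclusion are fallbacks. Gazetteer terms map to
#' `excision` or one of the four diagnostic sampling biopsy types
#' (punch, incision, shave, curettage); nothing found gives `unknown`.
#'
#' @inheritParams extract_diagnosis
#' @return List with `excision_type` and `evidence`.
#' @export
extract_excision_type <- function(segment) {
  for (sec in c("macroscopic", "microscopic", "conclusion")) {
    txt <- segment$sections[[sec]]
    if (!nzchar(txt)) next
    spans <- tag_concepts(txt, "excision_type", section = sec)
    if (length(spans) == 0L) next
    vals <- .gaz_value("excision_type",
                       vapply(spans, `[[`, "", "rule_id"))
    # a biopsy term wins over a generic excision term within one section
    pick <- if (any(vals %in% .BIOPSY_TYPES)) {
      which(vals %in% .BIOPSY_TYPES)[1L]
    } else 1L
    return(list(excision_type = vals[pick], evidence = spans[pick]))
  }
  list(excision_type = "unknown", evidence = list())
}

.MARGIN_NUM_PAT <- paste0(
  "(?i)\\b(?:nearest\\s+)?(peripheral|deep)\\s+",
  "(?:margin|clearance)\\b[^.;0-9]{0,40}?",
  "(\\d+(?:\\.\\d+)?)\\s*mm")

.MARGIN_MALFORMED_PAT <- paste0(
  "(?i)\\b(peripheral|deep)\\s+(?:margin|clearance)",
  "[^.;0-9]{0,40}?\\d+\\.\\.")

#' Extract margin statuses and distances
#'
#' Margins follow the reporting convention: clear when the nearest distance
#' exceeds 0 mm, involved at 0 mm. Numeric statements
#' ("nearest peripheral margin 0.5 mm") set the distance and hence the
#' status; lexical statements ("completely excised", "extends to the deep
#' margin", "incompletely excised") set statuses only. Numeric evidence
#' outranks lexical on conflict; an unmentioned margin is `not_stated`.
#' The microscopic description is scanned before the conclusion.
#'
#' @inheritParams extract_diagnosis
#' @return List with `peripheral_margin`, `deep_margin`,
#'   `peripheral_margin_mm`, `deep_margin_mm` and `evidence`.
#' @export
extract_margins <- function(segment) {
  num <- list(peripheral = NA_real_, deep = NA_real_)
  lex <- list(peripheral = NA_character_, deep = NA_character_)
  evidence <- list()
  for (sec in c("microscopic", "conclusion")) {
    txt <- .nfkc(segment$sections[[sec]])
    if (!nzchar(txt)) next
    if (grepl(.MARGIN_MALFORMED_PAT, txt, perl = TRUE)) {
      warning("malformed margin distance skipped in ", sec, " section",
              call. = FALSE)
    }
    m <- gregexpr(.MARGIN_NUM_PAT, txt, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
      for (j in seq_along(m)) {
        side <- tolower(substring(txt, cs[j, 1], cs[j, 1] + cl[j, 1] - 1L))
        mm <- as.numeric(substring(txt, cs[j, 2], cs[j, 2] + cl[j, 2] - 1L))
        if (is.na(num[[side]])) {
          num[[side]] <- mm
          evidence <- c(evidence, list(evidence_span(
            sec, as.integer(m[j]) - 1L,
            as.integer(m[j]) - 1L + attr(m, "match.length")[j],
            substr(txt, m[j], m[j] + attr(m, "match.length")[j] - 1L),
            paste0("mar_num_", side))))
        }
      }
    }
    spans <- tag_concepts(txt, "margin", section = sec)
    for (sp in spans) {
      val <- .gaz_value("margin", sp$rule_id)
      sides <- switch(val,
        clear_both = c("peripheral", "deep"),
        involved_peripheral = "peripheral",
        involved_deep = "deep",
        involved_lex = {
          sb <- .sentence_bounds(txt, sp$start)
          sent <- tolower(substr(txt, sb[1], sb[2]))
          named <- c("peripheral", "deep")[c(grepl("peripheral", sent),
                                             grepl("deep", sent))]
          if (length(named) > 0L) named else c("peripheral", "deep")
        })
      status <- if (val == "clear_both") "clear" else "involved"
      used <- FALSE
      for (side in sides) {
        cur <- lex[[side]]
        # lexical 'involved' beats lexical 'clear'; first wins otherwise
        if (is.na(cur) || (cur == "clear" && status == "involved")) {
          lex[[side]] <- status
          used <- TRUE
        }
      }
      if (used) evidence <- c(evidence, list(sp))
    }
  }
  out <- list()
  for (side in c("peripheral", "deep")) {
    if (!is.na(num[[side]])) {
      out[[paste0(side, "_margin")]] <-
        if (num[[side]] > 0) "clear" else "involved"
      out[[paste0(side, "_margin_mm")]] <- num[[side]]
    } else {
      out[[paste0(side, "_margin")]] <-
        if (!is.na(lex[[side]])) lex[[side]] else "not_stated"
      out[[paste0(side, "_margin_mm")]] <- NA_real_
    }
  }
  out$evidence <- evidence
  out
}

#' Extract recurrence status
#'
#' A lesion is recurrent when a non-negated recurrence cue ("recurrent",
#' "recurrence", "previously excised", "re-presentation") appears in the
#' clinical details or conclusion; the default is primary.
#'
#' @inheritParams extract_diagnosis
#' @param clinical_details_text Clinical-details text view for the segment
#'   (defaults to the segment's own view).
#' @return List with `recurrent` (logical) and `evidence`.
#' @export
extract_recurrence <- function(segment,
                               clinical_details_text =
                                 segment$sections$clinical_details) {
  sources <- list(clinical_details = clinical_details_text,
                  conclusion = segment$sections$conclusion)
  for (sec in names(sources)) {
    txt <- sources[[sec]]
    if (is.null(txt) || !nzchar(txt)) next
    spans <- tag_concepts(txt, "recurrence", section = sec)
    if (length(spans) == 0L) next
    neg <- vapply(spans, detect_negation, logical(1), section_text = txt)
    if (any(!neg)) {
      return(list(recurrent = TRUE, evidence = spans[!neg]))
    }
  }
  list(recurrent = FALSE, evidence = list())
}

.SUPPLEMENTAL_PAT <- "(?i)\\b(re-?\\s?excision|further excision|cavity)\\b"

.detect_supplemental <- function(segment) {
  for (sec in c("clinical_details", "macroscopic")) {
    txt <- .nfkc(segment$sections[[sec]])
    if (!nzchar(txt)) next
    m <- regexpr(.SUPPLEMENTAL_PAT, txt, perl = TRUE)
    if (m[1] != -1L) {
      return(list(supplemental = TRUE, evidence = list(evidence_span(
        sec, as.integer(m) - 1L, as.integer(m) - 1L + attr(m, "match.length"),
        substr(txt, m, m + attr(m, "match.length") - 1L), "sup_cue"))))
    }
  }
  list(supplemental = FALSE, evidence = list())
}

#' Assemble structured lesion records from a report
#'
#' Runs specimen segmentation and the field extractors, producing one
#' [lesion_record()] per specimen. Deterministic for a fixed input.
#'
#' @param report A [raw_report()].
#' @return List of `lesion_record` objects (empty, with a warning, for a
#'   blank report).
#' @export
#' @examples
#' r <- raw_report("R1", "P1",
#'   macroscopic = "Ellipse of skin 12 x 6 mm.",
#'   conclusion = "Nodular basal cell carcinoma, completely excised.")
#' assemble_records(r)
assemble_records <- function(report) {
  stopifnot(inherits(report, "raw_report"))
  if (!nzchar(trimws(report$raw_text))) {
    warning("report contains no text; no records extracted", call. = FALSE)
    return(list())
  }
  segments <- segment_specimens(report)
  lapply(segments, function(seg) {
    dx <- extract_diagnosis(seg)
    ex <- extract_excision_type(seg)
    mg <- extract_margins(seg)
    rc <- extract_recurrence(seg)
    sup <- .detect_supplemental(seg)
    lesion_record(
      specimen_label = seg$specimen_label,
      diagnosis_class = dx$diagnosis_class,
      bcc_subtype = if (dx$diagnosis_class == "bcc") dx$bcc_subtype else NA,
      excision_type = ex$excision_type,
      peripheral_margin = mg$peripheral_margin,
      deep_margin = mg$deep_margin,
      peripheral_margin_mm = mg$peripheral_margin_mm,
      deep_margin_mm = mg$deep_margin_mm,
      recurrent = rc$recurrent,
      supplemental = sup$supplemental,
      evidence = c(dx$evidence, ex$evidence, mg$evidence, rc$evidence,
                   sup$evidence))
  })
}
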