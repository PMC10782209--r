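## Synthetic histopathology corpus generator. Emits labelled reports under
## the four canonical subheadings, with gold lesion records, lesion
## outcomes and a patient-level recommendation per case, so the whole
## extract -> decide -> evaluate pipeline can be exercised without any
## clinical data. Every gold attribute is realised in the text by one of
## several phrasings; lexical noise rewords or adds distractor sentences
## but never removes a gold realisation.

.DEFAULT_MIXTURE <- c(
  follow_up_5y = 146, further_surgery = 31, no_follow_up = 770,
  re_excision = 45, review = 53)

.DEFAULT_LESION_DIST <- c(`1` = 0.80, `2` = 0.14, `3` = 0.04, `4` = 0.02)

#' Synthetic corpus generation configuration
#'
#' The default class mixture follows the reference-class marginals of the
#' validation cohort (146 : 31 : 770 : 45 : 53 over 1045 lesion episodes),
#' preserving the class imbalance that motivates micro-averaged
#' evaluation.
#'
#' @param n_patients Number of cases to generate (positive integer).
#' @param class_mixture Named non-negative weights over the five
#'   recommendation keys (normalised internally).
#' @param lesions_per_patient_distribution Named probabilities over lesion
#'   counts 1..4; must sum to 1.
#' @param noise_level Probability in `[0, 1]` of perturbing each sentence
#'   (hedging, safe synonym swap, spelling flip, benign distractor).
#' @param seed Master seed; per-patient streams are derived from it so the
#'   corpus is a pure function of the config.
#' @param template_set_id Report template collection (only `"default"` is
#'   packaged).
#' @return A `generation_config` list.
#' @export
generation_config <- function(n_patients,
                              class_mixture = .DEFAULT_MIXTURE,
                              lesions_per_patient_distribution =
                                .DEFAULT_LESION_DIST,
                              noise_level = 0,
                              seed = 1L,
                              template_set_id = "default") {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  bad <- setdiff(names(class_mixture), names(.REC_LABELS))
  if (length(bad) > 0L) {
    stop("class_mixture names unknown recommendation class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(class_mixture < 0) || sum(class_mixture) <= 0) {
    stop("class_mixture weights must be non-negative with a positive sum",
         call. = FALSE)
  }
  ld <- lesions_per_patient_distribution
  if (!all(names(ld) %in% as.character(1:4)) ||
      abs(sum(ld) - 1) > 1e-9 || any(ld < 0)) {
    stop("lesions_per_patient_distribution must be probabilities over ",
         "counts 1..4 summing to 1", call. = FALSE)
  }
  if (noise_level < 0 || noise_level > 1) {
    stop("noise_level must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(template_set_id, "default")) {
    stop("unknown template_set_id: ", template_set_id, call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("seed must be a single whole number", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         class_mixture = class_mixture / sum(class_mixture),
         lesions_per_patient_distribution = ld,
         noise_level = noise_level,
         seed = as.integer(seed),
         template_set_id = template_set_id),
    class = "generation_config")
}

.SITES <- c("left temple", "right temple", "left cheek", "right cheek",
            "nasal tip", "forehead", "left forearm", "right forearm",
            "back", "scalp", "left shoulder", "chin")

.BCC_SUBTYPES <- c("nodular", "superficial", "infiltrative",
                   "micronodular", "morphoeic")

.BENIGN_TERMS <- c("seborrhoeic keratosis", "dermatofibroma",
                   "intradermal naevus", "compound naevus",
                   "epidermal cyst", "viral wart")

.OTHER_DX <- list(
  other_cancer = c("squamous cell carcinoma", "malignant melanoma",
                   "merkel cell carcinoma"),
  other_in_situ = c("squamous cell carcinoma in situ", "melanoma in situ",
                    "lentigo maligna"),
  other_intermediate = c("keratoacanthoma", "atypical fibroxanthoma"))

.pick <- function(x) x[[sample.int(length(x), 1L)]]

.sample_mm <- function() round(stats::runif(1, 0.2, 5), 1)

# --- gold lesion builders ---------------------------------------------------

.margin_profile <- function(kind) {
  # kind: clear, peri_involved, deep_involved, both_involved, not_stated
  numeric_mode <- sample(c(TRUE, FALSE), 1L)
  switch(kind,
    clear = if (numeric_mode) {
      list(p = "clear", d = "clear", pmm = .sample_mm(), dmm = .sample_mm())
    } else {
      list(p = "clear", d = "clear", pmm = NA_real_, dmm = NA_real_)
    },
    peri_involved = if (numeric_mode) {
      list(p = "involved", d = "clear", pmm = 0, dmm = .sample_mm())
    } else {
      list(p = "involved", d = "not_stated", pmm = NA_real_, dmm = NA_real_)
    },
    deep_involved = if (numeric_mode) {
      list(p = "clear", d = "involved", pmm = .sample_mm(), dmm = 0)
    } else {
      list(p = "not_stated", d = "involved", pmm = NA_real_, dmm = NA_real_)
    },
    both_involved = list(p = "involved", d = "involved",
                         pmm = NA_real_, dmm = NA_real_),
    not_stated = list(p = "not_stated", d = "not_stated",
                      pmm = NA_real_, dmm = NA_real_))
}

.gold_bcc <- function(label, margin_kind, excision_type = "excision",
                      recurrent = FALSE, supplemental = FALSE) {
  mp <- .margin_profile(margin_kind)
  subtype <- if (stats::runif(1) < 0.7) .pick(.BCC_SUBTYPES) else NA_character_
  lesion_record(
    specimen_label = label, diagnosis_class = "bcc", bcc_subtype = subtype,
    excision_type = excision_type,
    peripheral_margin = mp$p, deep_margin = mp$d,
    peripheral_margin_mm = mp$pmm, deep_margin_mm = mp$dmm,
    recurrent = recurrent, supplemental = supplemental)
}

.gold_benign <- function(label) {
  stated <- sample(c(TRUE, FALSE), 1L)
  lesion_record(
    specimen_label = label, diagnosis_class = "benign",
    excision_type = "excision",
    peripheral_margin = if (stated) "clear" else "not_stated",
    deep_margin = if (stated) "clear" else "not_stated")
}

.gold_non_specific <- function(label) {
  lesion_record(specimen_label = label, diagnosis_class = "non_specific",
                excision_type = "excision")
}

.gold_other <- function(label) {
  cls <- .pick(names(.OTHER_DX))
  stated <- cls == "other_cancer" && stats::runif(1) < 0.5
  rec <- lesion_record(
    specimen_label = label, diagnosis_class = cls,
    excision_type = "excision",
    peripheral_margin = if (stated) "clear" else "not_stated",
    deep_margin = if (stated) "clear" else "not_stated")
  attr(rec, "dx_term") <- .pick(.OTHER_DX[[cls]])
  rec
}

#' Sample a gold case for a target recommendation class
#'
#' Builds lesions whose attributes (diagnosis class, margins, excision
#' type, recurrence, multiplicity) are mutually consistent with the target
#' recommendation under the guideline rule table. Uses R's global RNG;
#' callers (see [generate_corpus()]) seed it per patient.
#'
#' @param target_class One of the five recommendation classes (canonical
#'   label or short key).
#' @param config A [generation_config()] (controls the lesion-count
#'   distribution).
#' @param patient_id Identifier for the case.
#' @return A `gold_case`: list with `patient_id`, `lesions`,
#'   `expected_lesion_outcomes` (codes) and `expected_recommendation`
#'   (canonical label).
#' @export
sample_case <- function(target_class, config = generation_config(1),
                        patient_id = "P0001") {
  key <- if (target_class %in% names(.REC_LABELS)) target_class
         else recommendation_key(target_class)
  ld <- config$lesions_per_patient_distribution
  n_lesions <- as.integer(sample(names(ld), 1L, prob = ld))
  labels <- if (n_lesions == 1L) "1" else LETTERS[seq_len(n_lesions)]
  pad_benign <- function(core, core_outcomes) {
    n_extra <- n_lesions - length(core)
    if (n_extra > 0L) {
      extra_labels <- labels[(length(core) + 1L):n_lesions]
      core <- c(core, lapply(extra_labels, .gold_benign))
      core_outcomes <- c(core_outcomes,
                         rep("benign_or_non_specific", n_extra))
    }
    list(lesions = core, outcomes = core_outcomes)
  }
  built <- switch(key,
    no_follow_up = {
      variant <- .pick(c("complete_bcc", "benign", "supplemental_negative",
                         "non_specific"))
      switch(variant,
        complete_bcc = pad_benign(
          list(.gold_bcc(labels[1], "clear")), "complete_single_bcc"),
        benign = list(lesions = lapply(labels, .gold_benign),
                      outcomes = rep("benign_or_non_specific", n_lesions)),
        supplemental_negative = {
          rec <- .gold_bcc(labels[1], "clear", supplemental = TRUE)
          code <- if (rec$peripheral_margin == "clear")
            "supplemental_peripheral_negative" else "supplemental_deep_negative"
          pad_benign(list(rec), code)
        },
        non_specific = pad_benign(
          list(.gold_non_specific(labels[1])), "benign_or_non_specific"))
    },
    follow_up_5y = {
      multiple_ok <- n_lesions >= 2L
      variant <- if (multiple_ok) .pick(c("multiple", "recurrent"))
                 else "recurrent"
      if (variant == "multiple") {
        list(lesions = lapply(labels, function(l) .gold_bcc(l, "clear")),
             outcomes = rep("complete_single_bcc", n_lesions))
      } else {
        pad_benign(list(.gold_bcc(labels[1], "clear", recurrent = TRUE)),
                   "recurrent_bcc")
      }
    },
    re_excision = {
      variant <- .pick(c("incomplete", "supplemental_positive"))
      if (variant == "incomplete") {
        kind <- .pick(c("peri_involved", "deep_involved", "both_involved"))
        pad_benign(list(.gold_bcc(labels[1], kind)), "incomplete_bcc")
      } else {
        kind <- .pick(c("peri_involved", "deep_involved"))
        rec <- .gold_bcc(labels[1], kind, supplemental = TRUE)
        code <- if (rec$peripheral_margin == "involved")
          "supplemental_peripheral_positive" else "supplemental_deep_positive"
        pad_benign(list(rec), code)
      }
    },
    further_surgery = {
      btype <- .pick(.BIOPSY_TYPES)
      pad_benign(
        list(.gold_bcc(labels[1], "not_stated", excision_type = btype)),
        "diagnostic_biopsy_bcc")
    },
    review = pad_benign(list(.gold_other(labels[1])),
                        "other_cancer_in_situ_intermediate"),
    stop("unreachable recommendation class in sample_case: ", target_class,
         call. = FALSE))
  outcomes <- built$outcomes
  n_bcc <- sum(vapply(built$lesions,
                      function(r) r$diagnosis_class == "bcc", logical(1)))
  if (n_bcc >= 2L) outcomes <- c(outcomes, "multiple_bccs")
  structure(
    list(patient_id = patient_id,
         lesions = built$lesions,
         expected_lesion_outcomes = outcomes,
         expected_recommendation = recommendation_label(key)),
    class = "gold_case")
}

# --- text realisation -------------------------------------------------------

.clinical_sentences <- function(rec, site) {
  if (rec$supplemental) {
    .pick(list(
      paste0("Re-excision of scar on the ", site, "."),
      paste0("Further excision of the previous surgical site, ", site, "."),
      paste0("Cavity margins from the ", site, ".")))
  } else if (rec$recurrent) {
    .pick(list(
      paste0("Recurrent BCC on the ", site, "."),
      paste0("Recurrence of a previously treated lesion on the ", site, "."),
      paste0("Previously excised BCC on the ", site,
             ", with re-presentation.")))
  } else {
    .pick(list(
      paste0("Lesion on the ", site, "."),
      paste0("Skin lesion, ", site, ", for histology."),
      paste0("Enlarging papule on the ", site, ".")))
  }
}

.macroscopic_sentences <- function(rec) {
  a <- sample(6:25, 1L); b <- sample(4:15, 1L); d <- sample(3:6, 1L)
  switch(rec$excision_type,
    excision = .pick(list(
      sprintf("Ellipse of skin %d x %d mm.", a, b),
      sprintf("Skin excision measuring %d x %d mm.", a, b),
      sprintf("Wide local excision specimen %d x %d mm.", a, b))),
    punch_biopsy = .pick(list(
      sprintf("Punch biopsy of skin %d mm.", d),
      sprintf("A %d mm punch biopsy of skin.", d),
      sprintf("Skin punch biopsy, %d mm diameter.", d))),
    incision_biopsy = .pick(list(
      sprintf("Incision biopsy of skin %d x %d mm.", a, b),
      sprintf("Incisional biopsy specimen %d x %d mm.", a, b),
      sprintf("An incision biopsy measuring %d x %d mm.", a, b))),
    shave_biopsy = .pick(list(
      sprintf("Shave biopsy of skin %d x %d mm.", a, b),
      sprintf("Shave specimen of skin %d x %d mm.", a, b),
      sprintf("Superficial shave of skin %d x %d mm.", a, b))),
    curettage = .pick(list(
      "Curettings of skin in multiple fragments.",
      "Curettage specimen in fragments.",
      "Multiple fragments of curetted skin.")),
    "Skin specimen.")
}

.dx_phrase <- function(rec) {
  switch(rec$diagnosis_class,
    bcc = {
      base <- .pick(c("basal cell carcinoma", "BCC"))
      if (!is.na(rec$bcc_subtype)) paste(rec$bcc_subtype, base) else base
    },
    benign = attr(rec, "dx_term") %||% .pick(.BENIGN_TERMS),
    other_cancer = ,
    other_in_situ = ,
    other_intermediate =
      attr(rec, "dx_term") %||% .pick(.OTHER_DX[[rec$diagnosis_class]]),
    non_specific = NA_character_)
}

.micro_margin_sentence <- function(rec) {
  p <- rec$peripheral_margin_mm; d <- rec$deep_margin_mm
  if (!is.na(p) && !is.na(d)) {
    .pick(list(
      sprintf(
        "The nearest peripheral margin is %g mm and the nearest deep margin is %g mm.",
        p, d),
      sprintf("Excision margins: peripheral margin %g mm, deep margin %g mm.",
              p, d),
      sprintf(
        "Peripheral margin clearance %g mm; deep margin clearance %g mm.",
        p, d)))
  } else if (rec$peripheral_margin == "involved" &&
             rec$deep_margin == "involved") {
    .pick(list("The lesion is incompletely excised.",
               "There is incomplete excision of the lesion."))
  } else if (rec$peripheral_margin == "involved") {
    .pick(list("The tumour extends to the peripheral margin.",
               "Tumour reaches the peripheral margin.",
               "There is tumour involving the peripheral margin."))
  } else if (rec$deep_margin == "involved") {
    .pick(list("The tumour extends to the deep margin.",
               "Tumour reaches the deep margin.",
               "There is tumour involving the deep margin."))
  } else if (rec$peripheral_margin == "clear") {
    .pick(list("The lesion is completely excised.",
               "Complete excision is confirmed.",
               "The tumour is clear of the margins."))
  } else {
    NA_character_
  }
}

.micro_sentences <- function(rec, dx) {
  out <- character(0)
  if (rec$diagnosis_class == "bcc") {
    lead <- if (rec$supplemental) "residual " else ""
    out <- c(out, .pick(list(
      sprintf("Sections show a %s%s.", lead, dx),
      sprintf("There is a %s%s arising in sun-damaged skin.", lead, dx),
      sprintf("Histology demonstrates a %s%s.", lead, dx))))
  } else if (rec$diagnosis_class == "non_specific") {
    out <- c(out, .pick(list(
      "Sections show scar tissue only.",
      "There is dermal scarring with no residual tumour.",
      "Sections show fibrosis and a healing wound.")))
  } else {
    out <- c(out, .pick(list(
      sprintf("Sections show a %s.", dx),
      sprintf("The appearances are those of a %s.", dx),
      sprintf("Histology demonstrates a %s.", dx))))
  }
  if (rec$diagnosis_class == "bcc" &&
      rec$excision_type %in% .BIOPSY_TYPES) {
    out <- c(out, .pick(list(
      "Margins are not assessable in this sampling specimen.",
      "Margin status cannot be evaluated on this material.")))
  } else if (rec$diagnosis_class == "bcc") {
    ms <- .micro_margin_sentence(rec)
    if (!is.na(ms)) out <- c(out, ms)
  }
  paste(out, collapse = " ")
}

.conclusion_margin_suffix <- function(rec) {
  pi <- rec$peripheral_margin == "involved"
  di <- rec$deep_margin == "involved"
  if (pi && di) "; incompletely excised."
  else if (pi) ", incompletely excised at the peripheral margin."
  else if (di) ", incompletely excised at the deep margin."
  else if (rec$peripheral_margin == "clear" && rec$deep_margin == "clear")
    ", completely excised."
  else "."
}

.conclusion_sentences <- function(rec, dx, site) {
  if (rec$diagnosis_class == "non_specific") {
    return(.pick(list(
      "Scar. No evidence of residual basal cell carcinoma.",
      "Scar tissue; no residual basal cell carcinoma.",
      "Healing wound with no evidence of basal cell carcinoma.")))
  }
  lead <- if (rec$diagnosis_class == "bcc" && rec$supplemental)
    "Residual " else ""
  dx_cap <- paste0(toupper(substr(dx, 1, 1)), substr(dx, 2, nchar(dx)))
  head_txt <- if (nzchar(lead)) paste0(lead, dx) else dx_cap
  if (rec$diagnosis_class == "bcc" &&
      rec$excision_type %in% .BIOPSY_TYPES) {
    paste0(head_txt, " on diagnostic biopsy.")
  } else {
    paste0(head_txt, .conclusion_margin_suffix(rec))
  }
}

# --- noise operators --------------------------------------------------------

.DISTRACTORS <- c(
  "There is moderate solar elastosis in the surrounding dermis.",
  "The overlying epidermis shows hyperkeratosis.",
  "Mild chronic inflammation is present in the dermis.",
  "The adjacent skin shows actinic damage.")

.SYNONYMS <- c(shows = "demonstrates", arising = "originating",
               present = "evident", measuring = "sized at")

.SPELLING_FLIPS <- c(tumour = "tumor", oedema = "edema", centre = "center")

.perturb_sentence <- function(sentence, noise_level) {
  if (noise_level <= 0 || stats::runif(1) >= noise_level) return(sentence)
  op <- .pick(c("hedge", "synonym", "spelling", "distractor"))
  switch(op,
    hedge = paste0(.pick(c("In my opinion, ", "It appears that ")), sentence),
    synonym = {
      for (w in names(.SYNONYMS)) {
        sentence <- sub(paste0("\\b", w, "\\b"), .SYNONYMS[[w]], sentence)
      }
      sentence
    },
    spelling = {
      for (w in names(.SPELLING_FLIPS)) {
        sentence <- gsub(paste0("\\b", w, "\\b"), .SPELLING_FLIPS[[w]],
                         sentence)
      }
      sentence
    },
    distractor = paste(sentence, .pick(.DISTRACTORS)))
}

.apply_noise <- function(text, noise_level) {
  if (!nzchar(text) || noise_level <= 0) return(text)
  sentences <- strsplit(text, "(?<=\\.)\\s+", perl = TRUE)[[1]]
  paste(vapply(sentences, .perturb_sentence, character(1),
               noise_level = noise_level), collapse = " ")
}

#' Render a gold case as a histopathology report
#'
#' Realises every gold attribute of every lesion as one of several
#' phrasings under the four canonical subheadings. At `noise_level` 0 the
#' text is deterministic given the RNG state; perturbations reword or add
#' benign distractor sentences but never delete a gold realisation.
#' Multi-lesion cases label specimens "A.", "B.", ... in each section.
#'
#' @param case A `gold_case` from [sample_case()].
#' @param config A [generation_config()].
#' @param report_id Identifier for the report.
#' @return A [raw_report()].
#' @export
render_report <- function(case, config = generation_config(1),
                          report_id = paste0("R_", case$patient_id)) {
  multi <- length(case$lesions) > 1L
  per_lesion <- lapply(case$lesions, function(rec) {
    site <- .pick(.SITES)
    dx <- .dx_phrase(rec)
    list(
      clinical_details = .clinical_sentences(rec, site),
      macroscopic = .macroscopic_sentences(rec),
      microscopic = .micro_sentences(rec, dx),
      conclusion = .conclusion_sentences(rec, dx, site))
  })
  sections <- lapply(.SECTION_NAMES, function(sec) {
    parts <- vapply(seq_along(per_lesion), function(i) {
      txt <- .apply_noise(per_lesion[[i]][[sec]], config$noise_level)
      if (multi) paste0(case$lesions[[i]]$specimen_label, ". ", txt) else txt
    }, character(1))
    paste(parts, collapse = " ")
  })
  names(sections) <- .SECTION_NAMES
  raw_report(report_id, case$patient_id,
             clinical_details = sections$clinical_details,
             macroscopic = sections$macroscopic,
             microscopic = sections$microscopic,
             conclusion = sections$conclusion)
}

.patient_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 1000003 * i) %% 2147483647)
}

#' Generate a labelled synthetic corpus
#'
#' Draws a recommendation class per patient from the class mixture, builds
#' a consistent gold case and renders its report. Each patient uses an RNG
#' stream derived arithmetically from the master seed and the patient
#' index, so regenerating a subset reproduces the same cases. The corpus
#' is a pure function of the config.
#'
#' @param config A [generation_config()].
#' @return A `smdt_corpus`: list with `reports` (list of [raw_report()]),
#'   `gold` (list of `gold_case`) and `manifest` (config, config hash and
#'   per-class counts).
#' @export
#' @examples
#' corpus <- generate_corpus(generation_config(5, seed = 42))
#' corpus$manifest$class_counts
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  keys <- names(config$class_mixture)
  reports <- vector("list", config$n_patients)
  gold <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(.patient_seed(config$seed, i))
    cls <- sample(keys, 1L, prob = config$class_mixture)
    pid <- sprintf("P%05d", i)
    case <- sample_case(cls, config, patient_id = pid)
    gold[[i]] <- case
    reports[[i]] <- render_report(case, config,
                                  report_id = sprintf("R%05d", i))
  }
  counts <- table(factor(
    vapply(gold, function(g) recommendation_key(g$expected_recommendation),
           character(1)),
    levels = names(.REC_LABELS)))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(fileext = ".json"); on.exit(unlink(tf))
  writeLines(cfg_json, tf)
  manifest <- list(
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tf)),
    n_patients = config$n_patients,
    class_counts = as.list(counts))
  structure(list(reports = reports, gold = gold, manifest = manifest),
            class = "smdt_corpus")
}

#' @export
print.smdt_corpus <- function(x, ...) {
  cat("<smdt_corpus> ", length(x$reports), " reports\n", sep = "")
  cc <- unlist(x$manifest$class_counts)
  for (k in names(cc)) cat(sprintf("  %-16s %d\n", k, cc[[k]]))
  invisible(x)
}
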