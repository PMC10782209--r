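# Independent oracles, deliberately implemented by routes different from
# the package code they cross-check.

# One-vs-rest metrics by brute force: expand the count matrix into
# individual (reference, prediction) pairs and count outcomes directly.
oracle_ovr_metrics <- function(counts, labels = rownames(counts)) {
  ref <- character(0); pred <- character(0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      n <- counts[i, j]
      if (n > 0) {
        pred <- c(pred, rep(labels[i], n))
        ref <- c(ref, rep(labels[j], n))
      }
    }
  }
  out <- lapply(labels, function(k) {
    tp <- sum(pred == k & ref == k)
    fp <- sum(pred == k & ref != k)
    fn <- sum(pred != k & ref == k)
    tn <- sum(pred != k & ref != k)
    div <- function(a, b) if (b > 0) a / b else NA_real_
    data.frame(class_label = k, tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = div(tp, tp + fn),
               specificity = div(tn, tn + fp),
               ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
               accuracy = (tp + tn) / length(ref),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Patient-level recommendation by enumeration of the guideline rule rows,
# mapping each lesion straight to a recommendation key and scanning an
# explicit priority list.
oracle_lesion_rec <- function(rec) {
  dx <- rec$diagnosis_class
  involved <- rec$peripheral_margin == "involved" ||
    rec$deep_margin == "involved"
  if (dx %in% c("other_cancer", "other_in_situ", "other_intermediate")) {
    return("review")
  }
  if (dx %in% c("benign", "non_specific")) return("no_follow_up")
  if (rec$excision_type %in%
      c("punch_biopsy", "incision_biopsy", "shave_biopsy", "curettage")) {
    return("further_surgery")
  }
  if (rec$supplemental) {
    return(if (involved) "re_excision" else "no_follow_up")
  }
  if (rec$recurrent) return("follow_up_5y")
  if (involved) return("re_excision")
  "no_follow_up"
}

oracle_patient_rec <- function(records) {
  keys <- vapply(records, oracle_lesion_rec, character(1))
  if (sum(vapply(records, function(r) r$diagnosis_class == "bcc",
                 logical(1))) >= 2L) {
    keys <- c(keys, "follow_up_5y")
  }
  for (k in c("review", "further_surgery", "re_excision", "follow_up_5y",
              "no_follow_up")) {
    if (k %in% keys) return(k)
  }
}

# Discretised per-lesion attribute lattice used for aggregation sweeps:
# 3 diagnoses x 2 excision types x 2 margin profiles x recurrent x
# supplemental = 48 states covering every rule interaction.
decision_lattice <- function() {
  grid <- expand.grid(
    dx = c("bcc", "benign", "other_cancer"),
    exc = c("excision", "punch_biopsy"),
    involved = c(FALSE, TRUE),
    recurrent = c(FALSE, TRUE),
    supplemental = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    lesion_record(
      specimen_label = as.character(i),
      diagnosis_class = g$dx, excision_type = g$exc,
      peripheral_margin = if (g$involved) "involved" else "clear",
      deep_margin = "clear",
      recurrent = g$recurrent, supplemental = g$supplemental)
  })
}

# Build lesion-record lists grouped by case from the packaged fixture.
fixture_cases <- function() {
  fix <- decision_case_fixture()
  lapply(split(fix, fix$case_id), function(g) {
    list(case_id = g$case_id[1],
         records = df_to_records(g),
         expected_outcomes = g$expected_outcome,
         expected_recommendation = g$expected_recommendation[1])
  })
}

rec_fields <- c("specimen_label", "diagnosis_class", "bcc_subtype",
                "excision_type", "peripheral_margin", "deep_margin",
                "peripheral_margin_mm", "deep_margin_mm", "recurrent",
                "supplemental")

records_identical <- function(a, b) {
  all(vapply(rec_fields, function(f) {
    x <- a[[f]]; y <- b[[f]]
    identical(x, y) || (length(x) == 1 && length(y) == 1 &&
                          is.na(x) && is.na(y)) ||
      isTRUE(all.equal(x, y))
  }, logical(1)))
}
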