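# Builds the two packaged fixtures:
#  - inst/extdata/table2_confusion_matrix.csv (printed validation matrix)
#  - inst/extdata/decision_cases.csv (hand-assigned structured cases)

labels <- c(
  "Follow-up 6-monthly for 5 years",
  "Further excisional surgery, destructive surgical or non-surgical technique recommended to obtain oncological clearance",
  "No follow-up",
  "Offer re-excision. If declined follow-up 6-monthly for 2 years",
  "Other cancerous, in situ or intermediate lesion. Review of histopathology free text required to guide management")
stopifnot(identical(labels, sort(labels)))  # printed order is lexicographic

counts <- matrix(c(
  138, 7, 12, 11, 3,
  0, 17, 1, 1, 0,
  8, 7, 745, 20, 4,
  0, 0, 5, 12, 0,
  0, 0, 7, 1, 46), nrow = 5, byrow = TRUE)
stopifnot(sum(counts) == 1045,
          all(colSums(counts) == c(146, 31, 770, 45, 53)),
          all(diag(counts) == c(138, 17, 745, 12, 46)))
df <- data.frame(prediction = labels, counts, check.names = FALSE)
colnames(df) <- c("prediction", labels)
write.csv(df, "inst/extdata/table2_confusion_matrix.csv",
          row.names = FALSE, fileEncoding = "UTF-8")

# ---- structured decision cases --------------------------------------------
# One row per lesion. Hand-assigned expected_outcome (lesion level) and
# expected_recommendation_key (case level) from the guideline rule table
# and the fixed rule order / precedence.

rows <- list()
n <- 0
add <- function(case_id, lesion = "1", dx = "bcc", sub = NA, exc = "excision",
                p = "not_stated", d = "not_stated", pmm = NA, dmm = NA,
                rec = FALSE, sup = FALSE, out, key) {
  n <<- n + 1
  rows[[n]] <<- data.frame(
    case_id = case_id, specimen_label = lesion, diagnosis_class = dx,
    bcc_subtype = sub, excision_type = exc,
    peripheral_margin = p, deep_margin = d,
    peripheral_margin_mm = pmm, deep_margin_mm = dmm,
    recurrent = rec, supplemental = sup,
    expected_outcome = out, expected_recommendation_key = key,
    stringsAsFactors = FALSE)
}

subs <- c("nodular", "superficial", "infiltrative", "micronodular",
          "morphoeic")

# G1: completely excised single BCC -> no follow-up (10)
mmp <- list(c(0.5, 1), c(1, 2), c(2.5, 3), c(4, 1.5), c(0.3, 0.8), c(3, 3))
for (i in 1:10) {
  num <- i <= 6
  add(sprintf("C1_%02d", i), dx = "bcc",
      sub = if (i %% 2) subs[(i %% 5) + 1] else NA,
      p = "clear", d = "clear",
      pmm = if (num) mmp[[i]][1] else NA,
      dmm = if (num) mmp[[i]][2] else NA,
      out = "complete_single_bcc", key = "no_follow_up")
}

# G2: incompletely excised BCC (peripheral, deep or both) -> re-excision (12)
g2 <- list(
  list(p = "involved", d = "clear",      pmm = 0,  dmm = 1),
  list(p = "involved", d = "not_stated", pmm = NA, dmm = NA),
  list(p = "clear",    d = "involved",   pmm = 1,  dmm = 0),
  list(p = "not_stated", d = "involved", pmm = NA, dmm = NA),
  list(p = "involved", d = "involved",   pmm = NA, dmm = NA),
  list(p = "involved", d = "involved",   pmm = 0,  dmm = 0),
  list(p = "involved", d = "clear",      pmm = 0,  dmm = 2.5),
  list(p = "clear",    d = "involved",   pmm = 0.4, dmm = 0),
  list(p = "involved", d = "not_stated", pmm = 0, dmm = NA),
  list(p = "not_stated", d = "involved", pmm = NA, dmm = 0),
  list(p = "involved", d = "involved",   pmm = NA, dmm = NA),
  list(p = "involved", d = "clear",      pmm = NA, dmm = 3))
for (i in seq_along(g2)) {
  g <- g2[[i]]
  add(sprintf("C2_%02d", i), dx = "bcc",
      sub = if (i %% 3 == 0) subs[(i %% 5) + 1] else NA,
      p = g$p, d = g$d, pmm = g$pmm, dmm = g$dmm,
      out = "incomplete_bcc", key = "re_excision")
}

# G3: multiple BCCs -> follow-up 5 years (10 cases, 2-3 lesions)
for (i in 1:10) {
  nl <- if (i <= 7) 2 else 3
  for (j in seq_len(nl)) {
    add(sprintf("C3_%02d", i), lesion = LETTERS[j], dx = "bcc",
        sub = if (j == 1) subs[(i %% 5) + 1] else NA,
        p = "clear", d = "clear",
        pmm = if (j == 1) 1 else NA, dmm = if (j == 1) 2 else NA,
        out = "complete_single_bcc", key = "follow_up_5y")
  }
}

# G4: recurrent BCC -> follow-up 5 years (10; two with involved margins,
# which the fixed rule order still routes to the recurrent row)
for (i in 1:10) {
  inv <- i > 8
  add(sprintf("C4_%02d", i), dx = "bcc",
      sub = if (i %% 2) subs[(i %% 5) + 1] else NA,
      p = if (inv) "involved" else "clear",
      d = if (inv) "clear" else "clear",
      pmm = if (inv) 0 else c(0.5, 1, 2, NA)[((i - 1) %% 4) + 1],
      dmm = if (inv) 1 else c(1, 2, 0.6, NA)[((i - 1) %% 4) + 1],
      rec = TRUE, out = "recurrent_bcc", key = "follow_up_5y")
}

# G5: supplemental BCC, peripheral margin positive -> re-excision (8)
g5 <- list(
  list(p = "involved", d = "clear",      pmm = 0,  dmm = 1),
  list(p = "involved", d = "not_stated", pmm = NA, dmm = NA),
  list(p = "involved", d = "clear",      pmm = 0,  dmm = 2),
  list(p = "involved", d = "not_stated", pmm = 0,  dmm = NA),
  list(p = "involved", d = "involved",   pmm = NA, dmm = NA),  # polarity: peripheral first
  list(p = "involved", d = "involved",   pmm = 0,  dmm = 0),
  list(p = "involved", d = "clear",      pmm = NA, dmm = 1.5),
  list(p = "involved", d = "not_stated", pmm = NA, dmm = NA))
for (i in seq_along(g5)) {
  g <- g5[[i]]
  add(sprintf("C5_%02d", i), dx = "bcc", sup = TRUE,
      p = g$p, d = g$d, pmm = g$pmm, dmm = g$dmm,
      out = "supplemental_peripheral_positive", key = "re_excision")
}

# G6: supplemental BCC, peripheral margin negative -> no follow-up (8)
for (i in 1:8) {
  num <- i <= 4
  add(sprintf("C6_%02d", i), dx = "bcc", sup = TRUE,
      p = "clear", d = if (i %% 2) "clear" else "not_stated",
      pmm = if (num) c(0.5, 1, 2, 3)[i] else NA,
      dmm = if (num && i %% 2) c(1, 2, 3, 4)[i] else NA,
      out = "supplemental_peripheral_negative", key = "no_follow_up")
}

# G7: supplemental BCC, deep margin positive -> re-excision (8)
for (i in 1:8) {
  pstat <- if (i %% 2) "clear" else "not_stated"
  add(sprintf("C7_%02d", i), dx = "bcc", sup = TRUE,
      p = pstat, d = "involved",
      pmm = if (pstat == "clear" && i <= 4) 1 else NA,
      dmm = if (i <= 4) 0 else NA,
      out = "supplemental_deep_positive", key = "re_excision")
}

# G8: supplemental BCC, deep margin negative -> no follow-up (8)
for (i in 1:8) {
  add(sprintf("C8_%02d", i), dx = "bcc", sup = TRUE,
      p = "not_stated", d = if (i <= 6) "clear" else "not_stated",
      pmm = NA, dmm = if (i <= 4) c(1, 2, 0.5, 3)[i] else NA,
      out = "supplemental_deep_negative", key = "no_follow_up")
}

# G9: sampling biopsy with BCC -> further excisional surgery (12)
btypes <- c("punch_biopsy", "incision_biopsy", "shave_biopsy", "curettage")
for (i in 1:12) {
  bt <- btypes[((i - 1) %% 4) + 1]
  add(sprintf("C9_%02d", i), dx = "bcc",
      sub = if (i %% 3 == 0) subs[(i %% 5) + 1] else NA,
      exc = bt,
      rec = i == 11,   # biopsy rule precedes the recurrent rule
      sup = i == 12,   # ... and the supplemental rule
      out = "diagnostic_biopsy_bcc", key = "further_surgery")
}

# G10: benign or non-specific, any margin outcome -> no follow-up (12)
for (i in 1:12) {
  dx <- if (i > 9) "non_specific" else "benign"
  marg <- switch(((i - 1) %% 3) + 1,
                 list(p = "clear", d = "clear"),
                 list(p = "involved", d = "not_stated"),
                 list(p = "not_stated", d = "not_stated"))
  add(sprintf("C10_%02d", i), dx = dx,
      exc = if (i %% 4 == 0) "punch_biopsy" else "excision",
      p = marg$p, d = marg$d,
      out = "benign_or_non_specific", key = "no_follow_up")
}

# G11: any other cancer, in situ or intermediate -> review (12)
odx <- c("other_cancer", "other_in_situ", "other_intermediate")
for (i in 1:12) {
  marg <- switch(((i - 1) %% 3) + 1,
                 list(p = "clear", d = "clear"),
                 list(p = "involved", d = "involved"),
                 list(p = "not_stated", d = "not_stated"))
  add(sprintf("C11_%02d", i), dx = odx[((i - 1) %% 3) + 1],
      exc = if (i == 12) "shave_biopsy" else "excision",
      p = marg$p, d = marg$d, rec = i == 11,
      out = "other_cancer_in_situ_intermediate", key = "review")
}

# G12: multi-lesion precedence cases (8)
add("C12_01", "A", dx = "bcc", p = "clear", d = "clear", pmm = 1, dmm = 1,
    out = "complete_single_bcc", key = "no_follow_up")
add("C12_01", "B", dx = "benign", p = "clear", d = "clear",
    out = "benign_or_non_specific", key = "no_follow_up")

add("C12_02", "A", dx = "bcc", p = "involved", d = "clear", pmm = 0, dmm = 1,
    out = "incomplete_bcc", key = "re_excision")
add("C12_02", "B", dx = "bcc", p = "clear", d = "clear", pmm = 1, dmm = 1,
    out = "complete_single_bcc", key = "re_excision")

add("C12_03", "A", dx = "bcc", p = "clear", d = "clear", rec = TRUE,
    out = "recurrent_bcc", key = "re_excision")
add("C12_03", "B", dx = "bcc", p = "involved", d = "involved",
    out = "incomplete_bcc", key = "re_excision")

add("C12_04", "A", dx = "bcc", exc = "punch_biopsy",
    out = "diagnostic_biopsy_bcc", key = "further_surgery")
add("C12_04", "B", dx = "bcc", p = "clear", d = "clear", pmm = 2, dmm = 2,
    out = "complete_single_bcc", key = "further_surgery")

add("C12_05", "A", dx = "other_cancer", p = "clear", d = "clear",
    out = "other_cancer_in_situ_intermediate", key = "review")
add("C12_05", "B", dx = "bcc", p = "involved", d = "clear", pmm = 0, dmm = 1,
    out = "incomplete_bcc", key = "review")

add("C12_06", "A", dx = "benign",
    out = "benign_or_non_specific", key = "no_follow_up")
add("C12_06", "B", dx = "benign", p = "clear", d = "clear",
    out = "benign_or_non_specific", key = "no_follow_up")

for (j in 1:3) {
  add("C12_07", LETTERS[j], dx = "bcc", p = "clear", d = "clear",
      pmm = 1, dmm = 1, out = "complete_single_bcc", key = "follow_up_5y")
}

add("C12_08", "A", dx = "bcc", sup = TRUE, p = "involved", d = "not_stated",
    out = "supplemental_peripheral_positive", key = "re_excision")
add("C12_08", "B", dx = "benign", p = "clear", d = "clear",
    out = "benign_or_non_specific", key = "re_excision")

fix <- do.call(rbind, rows)
lesion_codes <- c(
  "complete_single_bcc", "incomplete_bcc", "recurrent_bcc",
  "supplemental_peripheral_positive", "supplemental_peripheral_negative",
  "supplemental_deep_positive", "supplemental_deep_negative",
  "diagnostic_biopsy_bcc", "benign_or_non_specific",
  "other_cancer_in_situ_intermediate")
stopifnot(length(unique(fix$case_id)) == 118,
          setequal(unique(fix$expected_outcome), lesion_codes))
write.csv(fix, "inst/extdata/decision_cases.csv",
          row.names = FALSE, fileEncoding = "UTF-8")
cat("cases:", length(unique(fix$case_id)), "lesion rows:", nrow(fix), "\n")
cat("outcome coverage:\n")
print(table(fix$expected_outcome))
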