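---
title: "Methods: a rule-based virtual skin MDT for BCC histopathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based virtual skin MDT for BCC histopathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinmdt)
```

# Scope and model

`skinmdt` models the decision step that a skin multidisciplinary team (MDT)
performs after surgery for basal cell carcinoma (BCC): read the
histopathology report, classify what happened to each lesion, and issue one
of five management recommendations. The package contains four cooperating
parts:

1. a **synthetic corpus generator** that produces labelled BCC
   histopathology reports;
2. a **rule-based extraction engine** that converts report text into
   structured lesion records with character-offset evidence spans;
3. a **decision engine** that maps lesion records to guideline outcome
   codes and aggregates them into a single patient-level recommendation
   plus a patient letter;
4. an **evaluation module** implementing one-versus-rest multiclass
   metrics, Cohen's kappa and diagnostic sample-size planning.

All components are deterministic given their inputs and a single seed.
No machine learning is involved anywhere: both the extraction and the
decision logic are explicit, inspectable rules. This is a design choice,
not a limitation of convenience — in a safety-relevant triage setting the
failure modes of a rule system are enumerable and auditable.

# The decision model

## Lesion outcome codes

Each lesion record carries a diagnosis class (`bcc`, `benign`,
`non_specific`, `other_cancer`, `other_in_situ`, `other_intermediate`), a
specimen type, peripheral and deep margin statuses, and flags for
recurrence and for supplementary (re-excision) specimens.
`classify_lesion_outcome()` assigns one of ten lesion-level outcome codes;
an eleventh, `multiple_bccs`, exists only at the patient level. The rules
are evaluated in a fixed order:

1. any non-BCC malignant, in-situ or intermediate lesion;
2. benign or non-specific findings;
3. BCC on a diagnostic (non-excisional) specimen;
4. supplementary specimens, split by which margin is involved
   (peripheral involvement outranks deep);
5. recurrent BCC;
6. BCC with any involved margin;
7. completely excised BCC.

The order is load-bearing. A recurrent BCC with involved margins is coded
`recurrent_bcc`, not `incomplete_bcc`; a biopsy of a recurrence is coded
`diagnostic_biopsy_bcc`. A BCC whose specimen type could not be determined
is treated as an excision, because excision is by far the commonest
surgical management and the conservative alternative (assuming a biopsy)
would escalate every under-specified report to further surgery.

## Patient aggregation

`aggregate_recommendation()` maps every outcome code to one of five
recommendations and resolves conflicts with a precedence order, highest
first: *review of free text* > *further surgery* > *re-excision* >
*5-year follow-up* > *no follow-up*. The ordering encodes clinical
severity: a recommendation is never downgraded by the presence of a more
benign co-existing lesion. Two or more BCCs in one episode additionally
contribute a `multiple_bccs` outcome (5-year follow-up). The precedence
is a parameter, so a service that prefers, say, re-excision over a
diagnostic-biopsy pathway can reorder it; the per-lesion outcome codes are
unaffected by that choice.

# The extraction model

Extraction is a classical gazetteer pipeline, deliberately simple:

* **Normalisation.** Report text is NFKC-normalised on construction, so
  that full-width or compatibility characters cannot bypass the matchers.
  All offsets are 0-based and end-exclusive.
* **Segmentation.** Multi-specimen reports using `A.`/`B.` (or numbered)
  markers are split per specimen; unlabelled sections are shared by all
  segments.
* **Concept tagging.** Terms come from editable CSV gazetteers
  (diagnosis, specimen type, margins, recurrence, negation cues). Matching
  is case-insensitive, bounded by non-alphanumerics, and longest-match
  wins, so "squamous cell carcinoma in situ" suppresses its invasive
  substring.
* **Negation.** A NegEx-style rule: a cue negates a concept when it
  precedes it in the same sentence within six tokens, and adversative
  conjunctions ("but", "however") terminate the scope.
* **Section priority.** The conclusion outranks the microscopic
  description for diagnosis; the macroscopic description is preferred for
  specimen type; recurrence is read from the clinical details or the
  conclusion.
* **Margins.** A measured distance in millimetres always outranks a
  lexical phrase: `mm > 0` means clear, `mm = 0` means involved. Among
  lexical cues, involvement phrases beat clearance phrases. Margins never
  mentioned stay `not_stated` — the extractor does not guess. This
  "numeric beats lexical" law is enforced as a record invariant by
  `validate_lesion_record()`, so inconsistent records cannot be
  constructed anywhere in the pipeline.

Supplementary specimens are recognised from re-excision cues ("re-excision",
"further excision", "cavity") in the clinical details or macroscopic text.

# The synthetic corpus generator

Because real histopathology reports cannot be redistributed, the package
ships a generator whose defaults are the study conditions used throughout
the tests.

* **Class mixture.** By default, patients are drawn so the expected
  recommendation follows the proportions 146 : 31 : 770 : 45 : 53 over
  (5-year follow-up, further surgery, no follow-up, re-excision, review),
  i.e. a heavily imbalanced mixture dominated by the no-follow-up class,
  as in routine practice. The mixture is a parameter.
* **Lesions per patient.** 1–4 lesions with default probabilities
  0.80 / 0.14 / 0.04 / 0.02; multi-lesion reports use `A.`, `B.` specimen
  labels.
* **Determinism.** Each patient's randomness is derived from the corpus
  seed by a fixed affine map modulo 2^31 − 1, so corpora are reproducible
  and insertion of additional patients does not shift earlier ones.
* **Margin realisation.** Whether a margin is reported numerically
  ("nearest peripheral margin 1 mm") or lexically ("completely excised")
  is decided in the gold record itself (`*_margin_mm` set or `NA`); the
  text renderer derives purely from the record. At noise level 0 the
  generator–extractor pair is therefore exactly invertible, which the
  round-trip tests exploit.
* **Noise.** `noise_level` in [0, 1] controls perturbations: hedging
  prefixes, safe synonym swaps, British/American spelling flips and benign
  distractor sentences. Noise never deletes or contradicts a gold
  realisation — it models stylistic variation, not transcription error,
  missing sections, OCR damage or genuinely ambiguous reports.
* **Scope.** The generator emits recurrent BCCs only with clear margins
  (a recurrent lesion with involved margins is still coded
  `recurrent_bcc`, so such text would test nothing new), and its templates
  never produce a `supplemental_deep_negative` realisation (deep-only
  reporting on a clear supplementary specimen). That outcome row is
  covered by the structured case fixture instead.

# Evaluation choices

* **Confusion matrix orientation.** Rows are predictions, columns are the
  reference; the packaged validation matrix
  (`validation_confusion_matrix()`) follows the same convention.
* **One-versus-rest metrics.** Sensitivity, specificity, PPV, NPV and
  per-class accuracy are computed from TP/FP/FN/TN per class.
  Zero-denominator ratios are `NA`, and macro averages exclude them
  (reporting how many were excluded) rather than silently imputing 0 or 1.
  Micro accuracy is the trace over the total.
* **Rounding.** All stored values are full precision; `round_half_up()`
  (half away from zero) is applied only when formatting 2-decimal
  reports, matching the convention of printed clinical tables rather than
  `round()`'s banker's rounding.
* **Kappa.** `cohens_kappa()` supports the standard marginal chance model
  and a `fixed` model in which the caller supplies the chance-agreement
  probability, because published agreement figures are sometimes computed
  under an assumed uniform chance of agreement that cannot be recovered
  from marginals.
* **Sample size.** `sensitivity_sample_size()` implements the standard
  normal-approximation formula
  `n_cases = ceiling(z^2 * SN * (1 - SN) / delta^2)` with
  `n_total = ceiling(n_cases / prevalence)`. A stated "significance level
  of 0.95" is read as 95% two-sided confidence (z = 1.96). The case count
  is floored at 1 so degenerate precision requests remain well defined.
  `sample_size_from_cases()` exposes the cases→controls arithmetic
  separately for planning from an externally fixed case count.

# Verification strategy

The test suite avoids checking the implementation against itself:

* one-versus-rest metrics are compared to a brute-force oracle that
  expands the count matrix into individual label pairs and counts
  outcomes directly (and, separately, to `caret::confusionMatrix()`);
* the decision engine is compared to an independent enumeration oracle
  over every unordered combination of up to three lesions drawn from a
  48-state attribute lattice (20,824 case multisets), and to a packaged
  fixture of 118 hand-labelled structured cases covering every outcome
  row;
* generator and extractor are checked against each other by noise-free
  round trips (field-exact) and noisy round trips (recommendation-exact).

Problem sizes used in the property tests: 1,000 random 5-class matrices,
200-patient round-trip corpora, and the 20,824-case aggregation sweep.
Every empirical number asserted anywhere in the test suite is computed at
test time by package code or an oracle in the same run; the suite contains
no pasted-in results that the tests do not themselves compute.

# Worked example

```{r}
cfg <- generation_config(n_patients = 5, seed = 42)
corpus <- generate_corpus(cfg)
cat(corpus$reports[[1]]$raw_text)

records <- assemble_records(corpus$reports[[1]])
decision <- aggregate_recommendation(records,
                                     corpus$gold[[1]]$patient_id)
decision$recommendation
```

# Limitations

* The extraction grammar covers the synthetic templates plus common
  phrasing variants; it is not a general clinical NLP system and has not
  seen real reports. Vocabulary coverage is bounded by the CSV
  gazetteers.
* The generator's noise model is stylistic only (see above); performance
  on noisy synthetic text is therefore an upper bound, not an estimate of
  real-world accuracy.
* Margin semantics are binary per side (clear/involved/not stated); close
  margins, Mohs layers and multifocal involvement are out of scope.
* The decision engine implements one guideline mapping with a fixed rule
  order; it does not model clinician override, comorbidity, patient
  preference or non-surgical primary management.
* Recommendations are hard classes, so threshold-based analyses (ROC,
  calibration) do not apply; no confidence intervals are attached to the
  evaluation metrics.
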