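# skinmdt

Rule-based decision support for the post-surgical management of basal
cell carcinoma (BCC), modelled on a "virtual skin MDT": instead of every
routine histopathology report being discussed at a multidisciplinary team
meeting, the report text is read by a rule-based extraction engine, each
lesion is classified against a guideline table, and the patient episode
receives one of five management recommendations together with a patient
letter. Straightforward cases are handled automatically; anything outside
the rules' competence (other malignancies, in-situ and intermediate
lesions) is explicitly routed to human review of the free text rather
than guessed at.

The package contains four cooperating modules:

* **Synthetic corpus generation** — `generate_corpus()` produces
  reproducible, labelled BCC histopathology reports under the four
  canonical subheadings (clinical details, macroscopic, microscopic,
  conclusion), with a configurable class mixture, multi-lesion reports
  and a stylistic noise model. Real reports cannot be redistributed, so
  the generator is the package's data source.
* **Extraction** — `assemble_records()` turns report text into
  structured lesion records using CSV gazetteers, longest-match concept
  tagging, NegEx-style negation, per-specimen segmentation and a strict
  margin rule (a measured distance in mm always outranks wording;
  `0 mm` means involved). Every extracted attribute carries evidence
  spans back into the text.
* **Decision engine** — `classify_lesion_outcome()` maps each record to
  one of eleven guideline outcome codes in a fixed rule order;
  `aggregate_recommendation()` resolves multi-lesion episodes through a
  severity precedence and `generate_letter()` drafts the patient letter.
* **Evaluation** — one-versus-rest confusion-matrix metrics with
  micro/macro averaging and explicit `NA` handling for undefined ratios,
  Cohen's kappa (marginal or fixed chance model), presentation rounding
  (half-up), and diagnostic sample-size planning.

A packaged validation confusion matrix
(`validation_confusion_matrix()`, 1,045 lesions over the five
recommendation classes) and a 118-case structured decision fixture
(`decision_case_fixture()`) support the evaluation examples and the test
suite.

## Worked example

```r
library(skinmdt)

corpus <- generate_corpus(generation_config(n_patients = 5, seed = 42))
report <- corpus$reports[[2]]
for (s in names(report$subheadings))
  cat(toupper(s), ": ", report$subheadings[[s]], "\n", sep = "")
#> CLINICAL_DETAILS: Recurrence of a previously treated lesion on the left shoulder.
#> MACROSCOPIC: Ellipse of skin 25 x 13 mm.
#> MICROSCOPIC: Sections show a BCC. Peripheral margin clearance 2.4 mm; deep margin clearance 2.8 mm.
#> CONCLUSION: BCC, completely excised.

records <- assemble_records(report)
records_to_df(records)
#>   specimen_label diagnosis_class bcc_subtype excision_type peripheral_margin
#> 1              1             bcc        <NA>      excision             clear
#>   deep_margin peripheral_margin_mm deep_margin_mm recurrent supplemental
#> 1       clear                  2.4            2.8      TRUE        FALSE

aggregate_recommendation(records, "P00002")
#> <patient_decision> P00002
#>   recurrent_bcc [1]
#>   recommendation: Follow-up 6-monthly for 5 years
```

Despite complete excision, the recurrence cue in the clinical details
drives the episode to 5-year follow-up — margin involvement is only
consulted after the recurrence rule.

Evaluating a prediction run (here, replaying the packaged validation
matrix):

```r
cm <- validation_confusion_matrix()
aggregate_metrics(one_vs_rest_metrics(cm), cm)
#> <aggregate_metrics>
#>   micro accuracy:    0.92
#>   macro sensitivity: 0.72
#>   macro specificity: 0.96
#>   macro PPV:         0.84
#>   macro NPV:         0.97
#>   per class sensitivity: 0.95 0.55 0.97 0.27 0.87
```

The full generate → extract → decide → letters → evaluate chain is
available as `run_pipeline()` (configured in R, YAML or JSON) and as a
thin command-line tool, `inst/cli/skinmdt.R`, with subcommands
`generate`, `extract`, `decide`, `letters`, `evaluate` and `pipeline`
(exit status 0 on success, 2 on usage error, 1 on stage failure).

## License

MIT (see `LICENSE`).
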