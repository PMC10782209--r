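Package: skinmdt
Title: Virtual Skin Multidisciplinary Team Decisions from Basal Cell
    Carcinoma Histopathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based information extraction from basal cell carcinoma
    (BCC) histopathology reports, a guideline-mapped clinical decision
    engine that issues one of five management recommendations together
    with a patient letter, and a one-versus-rest multiclass evaluation
    framework (confusion matrix, sensitivity, specificity, predictive
    values, micro and macro averaging, Cohen's kappa, and diagnostic
    sample-size planning). Includes a synthetic report corpus generator
    with gold labels so the full extract-decide-evaluate pipeline can be
    exercised without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    caret,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
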