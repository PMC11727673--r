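Package: bwspref
Title: Best-Worst Scaling Analysis of Patient Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing, simulating and analysing best-worst
    scaling (BWS case 1, "object case") preference studies. Constructs
    balanced incomplete block designs for the choice sets, screens pilot
    Likert ratings into a final item catalog, simulates phase-stratified
    respondents whose picks follow latent item utilities, computes
    best-minus-worst counting scores with availability normalisation, and
    fits the conditional-logit (MaxDiff) model with effects coding to
    obtain per-item utilities, standard errors, confidence intervals and
    rankings, overall and by subgroup. Ships a paper-anchored preset
    emulating a quality-of-care study in total joint arthroplasty.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
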