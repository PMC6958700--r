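Package: bestdiary
Title: Scoring, Exacerbation Detection and Validation Analysis for the BEST Bronchiectasis Symptom Diary
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the BEST (Bronchiectasis Exacerbation and Symptom Tool)
    daily diary: item definitions and daily total scoring (0-26), validation and
    CSV input/output of longitudinal diary records, rolling median-of-prior-week
    symptom baselines, characterisation of reported (treated) exacerbations and
    rule-based detection of unreported exacerbations (a sustained rise of at
    least 3 points for at least 48 hours without treatment). Provides a
    synthetic cohort generator with planted exacerbation events and correlated
    anchor questionnaires (SGRQ, CAT, LCQ, six-minute walk) for end-to-end
    testing, and the validation statistics used to appraise such an instrument:
    convergent-validity regressions, minimal clinically important difference by
    half-SD, anchor-regression and exacerbation-onset methods, change-cutoff
    sensitivity/specificity, and within-subject variability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
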