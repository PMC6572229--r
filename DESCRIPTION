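Package: ppdetect
Title: Automated Detection of Polypathological Patients from ICD-9-CM
    Discharge Codes and Validation Against Clinical Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based identification of polypathological patients (PP)
    from ICD-9-CM coded hospital-discharge records (minimum basic data
    set, MBDS). A patient is flagged PP when coded diagnoses satisfy at
    least two of eight predefined clinical categories (A-H), each defined
    by ICD-9-CM code prefixes and ranges with exceptions. The package
    ships the category rulebook as an editable JSON catalog, adjudicates
    up-to-three clinician assessments into a 2-of-3 consensus reference
    standard, and computes the full concordance-validation toolkit:
    Cohen's kappa with asymptotic and Fleiss-Cohen-Everitt variances,
    observed agreement with Wilson intervals, sensitivity, specificity,
    predictive values, intraclass correlation of category counts,
    precision-based sample size for kappa studies, confusion-table
    reconstruction from rounded published metrics, and a synthetic MBDS
    cohort generator with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
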