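Package: eposcds
Title: Guideline-Based Clinical Decision Support for Rhinosinusitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based clinical decision support engine for acute and
    chronic rhinosinusitis. Encodes the EPOS 2012 criteria as a declarative
    if-then knowledge base evaluated by a generic forward-chaining inference
    engine, maps each diagnostic category to its guideline therapy class
    (decongestant, intranasal corticosteroid, antibiotic, macrolide trial),
    generates synthetic patient cohorts with a prescribed category structure,
    and computes clinician-concordance and treatment-distribution statistics.
    Includes a command-line interface for classifying patient records,
    simulating cohorts, and evaluating concordance against reference labels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
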