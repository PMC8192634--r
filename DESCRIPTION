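Package: pulmostage
Title: Rule-Based T-Staging of Pulmonary Tumors from Free-Text Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based natural language processing pipeline that reads
    free-text English chest CT and PET-CT staging reports and derives the
    primary-tumor T stage of the TNM classification (AJCC 8th edition).
    The pipeline cleans and sectionizes a report, segments sentences,
    tokenizes, matches SNOMED-CT-coded concept synonyms, assigns
    negation/uncertainty/historical context in the ConText style, extracts
    dimensioned tumor measurements, consolidates tumor findings, and maps
    tumor size, structure involvement and presence findings onto a
    versioned T-substage decision table. Annotations are kept as
    token-level standoff records interchanged as JSON. A seeded synthetic
    report generator with gold labels and a multi-class evaluation module
    (substage/stage/size-only accuracy, per-class precision/recall/F1,
    confusion matrices) make every stage testable without access to
    protected clinical text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
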