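Package: surnamekit
Title: Construction and Evaluation of Ethnicity Surname Lists by Phonetic Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating surname lists used to identify
    ethnic populations in vital-records and cancer-registry databases. Implements
    American Soundex phonetic blocking, Jaro-Winkler scored linkage of surname
    lists (with truncation-aware matching for lists cut at a fixed character
    length), rule-based filtering of birthplace-derived surname candidates by
    patronymic suffix morphology and length, provenance-tracked list assembly
    with a full audit trail, and evaluation against registry-style records via
    overlap reports, three-set Venn region counts, birthplace contingency tables
    and suffix-convention distributions. Includes a ground-truth-labelled
    synthetic vital-records generator so every stage is testable without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
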