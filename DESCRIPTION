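Package: ctarmkg
Title: Arm-Level Efficacy and Safety Results from Clinical Trial Registry XML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses legacy ClinicalTrials.gov registered-results XML into an
    arm-centered, analysis-ready representation. Each two-arm efficacy
    comparison is classified as statistically positive or negative from its
    p-value or confidence interval, analysis-section group titles are resolved
    into intervention versus comparator arms by text similarity to the study
    design section, outcome titles are typed as biomarker, patient-reported,
    or clinical endpoint via MeSH tree numbers, serious adverse events are
    matched to efficacy arms and summarised with a ratio-weighted category
    co-occurrence statistic, and everything is assembled into a typed
    knowledge graph with Neo4j, GraphML, JSONL and Cypher exports. A seeded
    synthetic-corpus generator with a ground-truth manifest makes the whole
    pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    jsonlite,
    rlang,
    igraph,
    withr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
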