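Package: allregistry
Title: Automated Construction and Quality Assessment of a Pediatric ALL
    Registry from Clinical Data Warehouse Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Specification-driven construction of a pediatric acute
    lymphoblastic leukemia (ALL) registry from heterogeneous clinical data
    warehouse (CDW) extracts. Provides a registry table-specification model
    with NOT NULL, primary-key and foreign-key validation; a deterministic
    synthetic-CDW generator in two institutional dialects with ground-truth
    error injection; an ETL engine with cohort selection and direct,
    multivariate and rule-based NLP transforms (ISCN karyotype chromosome
    counts and ploidy class, interphase FISH 'nuc ish' copy numbers,
    flow-cytometry immunophenotype); quantification of automated data
    extraction (ADE) proportions; and a five-dimension data-quality rule
    engine (completeness, validity, accuracy, uniqueness, consistency) with
    remediation policies, error-rate metrics and level grading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
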