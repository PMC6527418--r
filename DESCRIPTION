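Package: phelab
Title: Deep Phenotyping from LOINC-Coded Laboratory Results via the Human Phenotype Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts LOINC-coded laboratory test results carried as FHIR
    Observation resources into Human Phenotype Ontology (HPO) terms through a
    curated outcome-annotation map, aggregates the calls into per-patient deep
    phenotype profiles with ontology ancestor propagation, and screens each
    phenotype for association with binary clinical exposures by logistic
    regression. Includes a seeded synthetic-cohort generator with known ground
    truth so the full pipeline can be exercised end to end without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
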