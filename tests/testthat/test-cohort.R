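calls_for <- function(patient, term, n, loinc = "90001-1", negated = FALSE,
                      times = NULL) {
  tibble::tibble(
    obs_id = sprintf("%s-%s-%d", patient, term, seq_len(n)),
    subject_id = patient, loinc = loinc, outcome_system = "FHIR",
    outcome_code = if (negated) "N" else "H", hpo = term, negated = negated,
    time = times %||% rep(NA_character_, n)
  )
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("profiles implement the three-state presence semantics", {
  ont <- default_ontology()
  cfg <- analysis_config()
  calls <- dplyr::bind_rows(
    calls_for("p1", "HP:0001880", 3),
    calls_for("p2", "HP:0001880", 2),
    calls_for("p3", "HP:0002900", 1)
  )
  prof <- build_profiles(calls, ont, cfg)
  get <- function(p, t) prof$presence[prof$patient_id == p & prof$term == t]
  expect_equal(get("p1", "HP:0001880"), "PRESENT")
  expect_equal(get("p2", "HP:0001880"), "INDETERMINATE")
  expect_equal(get("p3", "HP:0002900"), "INDETERMINATE")
  # a term never assigned to a patient has no row: ABSENT by construction
  expect_equal(nrow(prof[prof$patient_id == "p3" & prof$term == "HP:0001880", ]), 0L)
  # propagation carries presence to ancestors
  expect_equal(get("p1", "HP:0020064"), "PRESENT")
  expect_equal(get("p2", "HP:0020064"), "INDETERMINATE")
})

test_that("the four-glucose worked example aggregates correctly", {
  m <- default_annotation_map()
  ont <- default_ontology()
  res <- convert_collection(parse_bundle(fig3_bundle())$observations, m)
  prof <- build_profiles(res$calls, ont, analysis_config())
  row <- prof[prof$term == "HP:0003074", ]
  expect_equal(row$asserted_count, 4L)
  expect_equal(row$n_loinc, 3L)
  expect_equal(row$presence, "PRESENT")
  expect_equal(substr(row$first_time, 1, 10), "2019-01-05")
  expect_equal(substr(row$last_time, 1, 10), "2019-04-20")
})

test_that("negated calls never propagate and never become PRESENT", {
  ont <- default_ontology()
  calls <- calls_for("p1", "HP:0011042", 5, loinc = "6298-4", negated = TRUE)
  prof <- build_profiles(calls, ont, analysis_config())
  expect_equal(nrow(prof), 1L)
  expect_true(prof$negated)
  expect_true(is.na(prof$presence))
  expect_true(is.na(prof$propagated_count))
  # the parent metabolism term acquired nothing
  expect_false("HP:0032245" %in% prof$term)
})

test_that("appending calls never demotes presence", {
  ont <- default_ontology()
  cfg <- analysis_config()
  rank <- c(ABSENT = 0, INDETERMINATE = 1, PRESENT = 2)
  base <- calls_for("p1", "HP:0001880", 2)
  more <- dplyr::bind_rows(base, calls_for("p1", "HP:0040087", 2),
                           calls_for("p1", "HP:0001880", 4))
  p1 <- build_profiles(base, ont, cfg)
  p2 <- build_profiles(more, ont, cfg)
  for (t in p1$term) {
    r1 <- rank[[p1$presence[p1$term == t]]]
    r2 <- rank[[p2$presence[p2$term == t]]]
    expect_gte(r2, r1)
  }
})

test_that("encounter-day exclusion uses the documented boundary", {
  cfg <- analysis_config()
  records <- build_patient_records(
    patients = tibble::tibble(patient_id = c("a", "b", "c")),
    encounters = tibble::tibble(
      patient_id = c(rep("a", 9), rep("b", 10)),
      date = c(as.Date("2010-01-01") + 0:8, as.Date("2010-01-01") + 0:9)),
    medications = tibble::tibble(patient_id = character(), date = as.Date(character()),
                                 drug_name = character()),
    diagnoses = tibble::tibble(patient_id = character(), date = as.Date(character()),
                               icd_version = character(), code = character()),
    cfg)
  out <- apply_exclusions(records, cfg)
  expect_false(out$retained[out$patient_id == "a"])   # 9 days
  expect_true(out$retained[out$patient_id == "b"])    # 10 days
  expect_false(out$retained[out$patient_id == "c"])   # no encounters
  expect_equal(out$exclusion_reason[out$patient_id == "a"], "FEW_ENCOUNTER_DAYS")

  # duplicate dates on one day count once; all record types contribute
  rec2 <- build_patient_records(
    patients = tibble::tibble(patient_id = "d"),
    encounters = tibble::tibble(patient_id = rep("d", 4),
                                date = as.Date("2010-01-01") + c(0, 0, 1, 2)),
    medications = tibble::tibble(patient_id = "d", date = as.Date("2010-02-01"),
                                 drug_name = "prednisone"),
    diagnoses = tibble::tibble(patient_id = "d", date = as.Date("2010-03-01"),
                               icd_version = "10", code = "J45.901"),
    cfg)
  expect_equal(rec2$n_encounter_days, 5L)
})

test_that("exposure flags use strict >3 prescriptions and ICD prefix matching", {
  cfg <- analysis_config()
  mk_rec <- function(rx, codes) {
    tibble::tibble(patient_id = "p", prednisone_rx_count = rx,
                   dx_codes = list(codes))
  }
  expect_false(flag_exposures(mk_rec(3L, character()), cfg)$frequent_prednisone)
  expect_true(flag_exposures(mk_rec(4L, character()), cfg)$frequent_prednisone)
  expect_true(flag_exposures(mk_rec(0L, "J45.901"), cfg)$acute_asthma)
  expect_true(flag_exposures(mk_rec(0L, "49302"), cfg)$acute_asthma)
  expect_false(flag_exposures(mk_rec(0L, "J44.9"), cfg)$acute_asthma)
})

test_that("profile summaries match an independent recount", {
  ont <- default_ontology()
  calls <- dplyr::bind_rows(
    calls_for("p1", "HP:0001880", 3),
    calls_for("p1", "HP:0002900", 1, loinc = "90004-4"),
    calls_for("p1", "HP:0011042", 2, loinc = "6298-4", negated = TRUE),
    calls_for("p2", "HP:0040087", 4, loinc = "90005-5")
  )
  prof <- build_profiles(calls, ont, analysis_config())
  s <- profile_summary(prof)
  # by hand: p1 asserted terms = {1880, 2900, 11042-negated} = 3;
  #          p2 asserted terms = {40087} = 1
  expect_equal(s$n_patients, 2L)
  expect_equal(s$mean_unique_terms, 2)
  expect_equal(s$mean_abnormalities, 1.5)
  expect_equal(sum(s$histogram$n_patients), 2L)

  empty <- profile_summary(build_profiles(calls[0, ], ont))
  expect_equal(empty$n_patients, 0L)
  expect_true(is.na(empty$mean_unique_terms))
})

test_that("cohort CSV dialect round-trips through the reader", {
  dir <- tempfile(); dir.create(dir)
  readr::write_csv(tibble::tibble(patient_id = "p1", sex = "F",
                                  birth_date = as.Date("1960-05-01")),
                   file.path(dir, "patients.csv"))
  readr::write_csv(tibble::tibble(patient_id = "p1",
                                  date = as.Date("2010-01-01")),
                   file.path(dir, "encounters.csv"))
  readr::write_csv(tibble::tibble(patient_id = "p1",
                                  date = as.Date("2010-01-01"),
                                  drug_name = "prednisone"),
                   file.path(dir, "medications.csv"))
  readr::write_csv(tibble::tibble(patient_id = "p1",
                                  date = as.Date("2010-01-01"),
                                  icd_version = "10", code = "J45.901"),
                   file.path(dir, "diagnoses.csv"))
  tabs <- read_cohort_csvs(dir)
  expect_equal(tabs$patients$patient_id, "p1")
  expect_s3_class(tabs$encounters$date, "Date")
  expect_error(read_cohort_csvs(tempfile()), "missing")
})
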