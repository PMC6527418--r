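test_that("interpretation normalization is total, case-insensitive and idempotent", {
  expect_equal(normalize_interpretation("LL"), "L")
  expect_equal(normalize_interpretation("DET"), "POS")
  expect_equal(normalize_interpretation("H"), "H")
  expect_equal(normalize_interpretation("<"), "L")
  expect_equal(normalize_interpretation(" hh "), "H")
  expect_equal(normalize_interpretation("null"), "U")
  expect_equal(normalize_interpretation("made-up-token"), "U")
  # idempotence over a broad token set
  tokens <- c("A", "AA", "W", "L", "<", "D", "LL", "LU", "N", "B", "I",
              "H", ">", "HH", "HU", "UH", "NEG", "ND", "NR", "POS", "AC",
              "DET", "RR", "TOX", "WR", "U", "HM", "null", "SYN-R", "zzz")
  once <- normalize_interpretation(tokens)
  expect_equal(normalize_interpretation(once), once)
})

test_that("range inference respects bounds, inclusivity and one-sided ranges", {
  expect_equal(infer_outcome_from_range(3.0, 3.5, 5.0), "L")
  expect_equal(infer_outcome_from_range(6.1, 3.5, 5.0), "H")
  expect_equal(infer_outcome_from_range(4.2, 3.5, 5.0), "N")
  # bounds are inclusive of normal
  expect_equal(infer_outcome_from_range(3.5, 3.5, 5.0), "N")
  expect_equal(infer_outcome_from_range(5.0, 3.5, 5.0), "N")
  # one-sided
  expect_equal(infer_outcome_from_range(10, NA, 5.0), "H")
  expect_equal(infer_outcome_from_range(10, 3.5, NA), "N")
  expect_true(is.na(infer_outcome_from_range(10, NA, NA)))
})

test_that("outcome resolution follows interpretation > coded value > range precedence", {
  m <- default_annotation_map()
  # interpretation code wins even with no value
  o1 <- make_obs(loinc = "6298-4", interp = "HH")
  r1 <- resolve_outcomes(o1, m)
  expect_equal(r1$outcome_code, "H")
  expect_equal(r1$outcome_system, "FHIR")
  # explicit unknown interpretation fails even with a usable numeric value
  o2 <- make_obs(loinc = "6298-4", value = 6.1, unit = "mmol/L",
                 low = 3.5, high = 5.0, interp = "IND")
  expect_equal(resolve_outcomes(o2, m)$failure, "UNKNOWN_INTERPRETATION")
  # Nom coded value -> external outcome key
  o3 <- make_obs(loinc = "5778-6", value_code = "371240000",
                 value_system = "http://snomed.info/sct")
  r3 <- resolve_outcomes(o3, m)
  expect_equal(r3$outcome_system, "http://snomed.info/sct")
  expect_equal(r3$outcome_code, "371240000")
  # Qn numeric + range -> inferred internal code
  o4 <- make_obs(loinc = "6298-4", value = 6.1, unit = "mmol/L",
                 low = 3.5, high = 5.0)
  expect_equal(resolve_outcomes(o4, m)$outcome_code, "H")
  # no usable information
  o5 <- make_obs(loinc = "6298-4")
  expect_equal(resolve_outcomes(o5, m)$failure, "INSUFFICIENT_DATA")
  # unit mismatch between value and range is not coerced
  o6 <- make_obs(loinc = "6298-4", value = 6.1, unit = "mmol/L",
                 low = 3.5, high = 5.0, runit = "mg/dL")
  expect_equal(resolve_outcomes(o6, m)$failure, "INSUFFICIENT_DATA")
})

test_that("conversion reproduces the potassium and glucose mappings", {
  m <- default_annotation_map()
  obs <- dplyr::bind_rows(
    make_obs("k-high", loinc = "6298-4", value = 6.1, unit = "mmol/L",
             low = 3.5, high = 5.0),
    make_obs("k-normal", loinc = "6298-4", value = 4.0, unit = "mmol/L",
             low = 3.5, high = 5.0),
    make_obs("glu-high", loinc = "15074-8", value = 180, unit = "mg/dL",
             low = 70, high = 100)
  )
  out <- convert_observations(obs, m)
  expect_equal(out$status, rep("CONVERTED", 3))
  expect_equal(out$hpo, c("HP:0002153", "HP:0011042", "HP:0003074"))
  expect_equal(out$negated, c(FALSE, TRUE, FALSE))
})

test_that("L/H falls back to an A annotation but N never does", {
  m <- annotation_map(tibble::tibble(
    loinc = "9000-1", scale = "Qn", outcome_system = "FHIR",
    outcome_code = "A", hpo = "HP:0011042", negated = FALSE))
  high <- make_obs(loinc = "9000-1", interp = "H")
  out <- convert_observations(high, m)
  expect_equal(out$status, "CONVERTED")
  expect_equal(out$hpo, "HP:0011042")
  normal <- make_obs(loinc = "9000-1", interp = "N")
  expect_equal(convert_observations(normal, m)$status, "UNMAPPED_OUTCOME")
})

test_that("interpretation wins over a conflicting range with a logged conflict", {
  m <- default_annotation_map()
  # code says H, range says N
  o <- make_obs(loinc = "6298-4", value = 4.0, unit = "mmol/L",
                low = 3.5, high = 5.0, interp = "H")
  expect_warning(out <- convert_observations(o, m),
                 class = "phelab_range_conflict")
  expect_equal(out$hpo, "HP:0002153")
  expect_true(out$range_conflict)
  # agreeing paths yield the same call with no conflict
  o2 <- make_obs(loinc = "6298-4", value = 6.1, unit = "mmol/L",
                 low = 3.5, high = 5.0, interp = "H")
  out2 <- convert_observations(o2, m)
  expect_false(out2$range_conflict)
  o3 <- make_obs(loinc = "6298-4", value = 6.1, unit = "mmol/L",
                 low = 3.5, high = 5.0)
  expect_equal(convert_observations(o3, m)$hpo, out2$hpo)
})

test_that("negated calls arise only from N/NEG outcomes", {
  m <- default_annotation_map()
  set.seed(31)
  obs <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_obs(paste0("o", i), loinc = sample(c("6298-4", "32710-6", "15074-8"), 1),
             interp = sample(c("H", "L", "N", "POS", "NEG", "A"), 1))
  }))
  out <- suppressWarnings(convert_observations(obs, m))
  conv <- out[out$status == "CONVERTED", ]
  expect_true(all(!conv$negated | conv$outcome_code %in% c("N", "NEG")))
})

test_that("collection conversion tallies match a per-record recount and order permutes", {
  m <- default_annotation_map()
  set.seed(17)
  mk <- function(i) {
    kind <- sample(c("ok_num", "ok_interp", "unmapped", "insufficient"), 1)
    if (kind == "ok_num") {
      make_obs(paste0("o", i), loinc = "6298-4",
               value = runif(1, 2, 7), unit = "mmol/L", low = 3.5, high = 5.0)
    } else if (kind == "ok_interp") {
      make_obs(paste0("o", i), loinc = "32710-6", interp = sample(c("POS", "NEG"), 1))
    } else if (kind == "unmapped") {
      make_obs(paste0("o", i), loinc = "99999-9", value = 1, unit = "x",
               low = 0, high = 2)
    } else {
      make_obs(paste0("o", i), loinc = "6298-4")
    }
  }
  obs <- dplyr::bind_rows(lapply(1:50, mk))
  res <- convert_collection(obs, m)
  expect_equal(nrow(res$calls) + nrow(res$failures), 50L)
  expect_equal(res$rate, nrow(res$calls) / 50)

  # independent recount: each record converted alone gives the same status
  solo_status <- vapply(1:50, function(i) {
    r <- convert_collection(obs[i, ], m)
    if (nrow(r$calls) == 1) "CONVERTED" else r$failures$reason
  }, character(1))
  whole <- convert_observations(obs, m)
  expect_equal(whole$status, solo_status)

  # permutation invariance
  perm <- sample(50)
  out_perm <- convert_observations(obs[perm, ], m)
  expect_equal(out_perm, whole[perm, ], ignore_attr = TRUE)

  # empty input
  empty <- convert_collection(obs[0, ], m)
  expect_equal(empty$rate, 0)
  expect_equal(nrow(empty$calls), 0L)
})
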