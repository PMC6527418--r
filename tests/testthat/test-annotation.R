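test_that("annotation TSV reading handles the worked examples", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment line",
    paste("loincId", "loincScale", "outcomeSystem", "outcomeCode",
          "hpoTermId", "isNegated", sep = "\t"),
    paste("6298-4", "Qn", "FHIR", "H", "HP:0002153", "false", sep = "\t")
  ), f)
  m <- read_annotation_tsv(f)
  expect_s3_class(m, "annotation_map")
  expect_equal(nrow(m), 1L)
  expect_equal(m$hpo, "HP:0002153")
  expect_false(m$negated)

  # header-only file -> empty map
  writeLines(paste("loincId", "loincScale", "outcomeSystem", "outcomeCode",
                   "hpoTermId", "isNegated", sep = "\t"), f)
  expect_equal(nrow(read_annotation_tsv(f)), 0L)
})

test_that("duplicate keys, bad ids and inconsistent scales are rejected with line numbers", {
  hdr <- paste("loincId", "loincScale", "outcomeSystem", "outcomeCode",
               "hpoTermId", "isNegated", sep = "\t")
  f <- tempfile(fileext = ".tsv")

  writeLines(c(hdr,
               paste("6298-4", "Qn", "FHIR", "H", "HP:0002153", "false", sep = "\t"),
               paste("6298-4", "Qn", "FHIR", "H", "HP:0002900", "false", sep = "\t")), f)
  expect_error(read_annotation_tsv(f), class = "phelab_duplicate_error")

  writeLines(c(hdr,
               paste("not-a-loinc!", "Qn", "FHIR", "H", "HP:0002153", "false", sep = "\t")), f)
  err <- tryCatch(read_annotation_tsv(f), error = function(e) e)
  expect_s3_class(err, "phelab_parse_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c(hdr,
               paste("6298-4", "Qn", "FHIR", "H", "HP:0002153", "false", sep = "\t"),
               paste("6298-4", "Ord", "FHIR", "POS", "HP:0002900", "false", sep = "\t")), f)
  expect_error(read_annotation_tsv(f), class = "phelab_consistency_error")

  # negation only for normal/absent outcomes
  expect_error(
    annotation_map(tibble::tibble(
      loinc = "6298-4", scale = "Qn", outcome_system = "FHIR",
      outcome_code = "H", hpo = "HP:0002153", negated = TRUE)),
    class = "phelab_parse_error")

  # 'U' is never a valid annotation key
  expect_error(
    annotation_map(tibble::tibble(
      loinc = "6298-4", scale = "Qn", outcome_system = "FHIR",
      outcome_code = "U", hpo = "HP:0002153", negated = FALSE)),
    class = "phelab_parse_error")
})

test_that("alias headers from upstream layouts are accepted, unknown layouts rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("loincId", "loincScale", "system", "code", "hpoTermId", "isNegated", sep = "\t"),
    paste("6298-4", "Qn", "FHIR", "L", "HP:0002900", "false", sep = "\t")
  ), f)
  m <- read_annotation_tsv(f)
  expect_equal(m$outcome_code, "L")
  expect_error(read_annotation_tsv(f, strict = TRUE), class = "phelab_parse_error")

  writeLines(c(paste("a", "b", "c", sep = "\t"),
               paste("1", "2", "3", sep = "\t")), f)
  expect_error(read_annotation_tsv(f), class = "phelab_parse_error")
})

test_that("TSV round-trip is the identity and writes are byte-deterministic", {
  for (seed in c(11, 12, 13)) {
    m <- random_annotation_map(25, seed)
    f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
    write_annotation_tsv(m, f1)
    m2 <- read_annotation_tsv(f1)
    sorted <- function(x) dplyr::arrange(tibble::as_tibble(x), loinc,
                                         outcome_system, outcome_code)
    expect_equal(sorted(m2), sorted(m))
    write_annotation_tsv(m2, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("extra columns survive the round trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("loincId", "loincScale", "outcomeSystem", "outcomeCode",
          "hpoTermId", "isNegated", "localNote", sep = "\t"),
    paste("6298-4", "Qn", "FHIR", "H", "HP:0002153", "false", "keepme", sep = "\t")
  ), f)
  m <- read_annotation_tsv(f)
  expect_equal(m$localNote, "keepme")
  f2 <- tempfile(fileext = ".tsv")
  write_annotation_tsv(m, f2)
  expect_equal(read_annotation_tsv(f2)$localNote, "keepme")
})

test_that("lookup distinguishes unmapped LOINC from unmapped outcome and matches a linear scan", {
  m <- default_annotation_map()
  expect_equal(annotation_lookup(m, "32710-6", "POS")$hpo, "HP:0031812")
  expect_false(annotation_lookup(m, "32710-6", "POS")$negated)
  expect_true(annotation_lookup(m, "32710-6", "NEG")$negated)
  expect_equal(annotation_lookup(m, "99999-9", "H")$status, "UNMAPPED_LOINC")
  expect_equal(annotation_lookup(m, "32710-6", "H")$status, "UNMAPPED_OUTCOME")

  # oracle equivalence with a linear scan over the entries
  m <- random_annotation_map(40, seed = 99)
  tbl <- tibble::as_tibble(m)
  set.seed(100)
  probe <- dplyr::bind_rows(
    dplyr::slice_sample(tbl[, c("loinc", "outcome_system", "outcome_code")], n = 30),
    tibble::tibble(loinc = "1-1", outcome_system = "FHIR", outcome_code = "H")
  )
  for (i in seq_len(nrow(probe))) {
    got <- annotation_lookup(m, probe$loinc[i], probe$outcome_code[i],
                             probe$outcome_system[i])
    scan <- tbl[tbl$loinc == probe$loinc[i] &
                  tbl$outcome_system == probe$outcome_system[i] &
                  tbl$outcome_code == probe$outcome_code[i], ]
    if (nrow(scan) == 1) {
      expect_equal(got$status, "FOUND")
      expect_equal(got$hpo, scan$hpo)
      expect_equal(got$negated, scan$negated)
    } else {
      expect_true(got$status %in% c("UNMAPPED_LOINC", "UNMAPPED_OUTCOME"))
      expect_equal(got$status == "UNMAPPED_OUTCOME",
                   probe$loinc[i] %in% tbl$loinc)
    }
  }
})

test_that("map statistics equal an independent recount and percentages sum to 100", {
  m <- random_annotation_map(10, seed = 7)
  s <- map_statistics(m)
  tbl <- tibble::as_tibble(m)
  # brute-force recount with base R only
  per_loinc <- unique(tbl[, c("loinc", "scale")])
  expect_equal(s$n_loinc, nrow(per_loinc))
  expect_equal(s$n_hpo, length(unique(tbl$hpo)))
  cnt <- table(factor(per_loinc$scale, levels = c("Qn", "Ord", "Nom")))
  expect_equal(s$by_scale$n, as.integer(cnt))
  lph <- tapply(tbl$loinc, tbl$hpo, function(x) length(unique(x)))
  expect_equal(s$mean_loinc_per_hpo, mean(lph))
  expect_equal(sum(s$by_scale$pct), 100, tolerance = 1e-3)

  # two LOINCs mapping to one HPO -> 1 distinct, mean 2
  m2 <- annotation_map(tibble::tibble(
    loinc = c("1000-1", "1001-2"), scale = "Ord", outcome_system = "FHIR",
    outcome_code = "POS", hpo = "HP:0031812", negated = FALSE))
  s2 <- map_statistics(m2)
  expect_equal(s2$n_hpo, 1L)
  expect_equal(s2$mean_loinc_per_hpo, 2)

  # empty map -> all-zero summary
  empty <- annotation_map(tibble::tibble(
    loinc = character(), scale = character(), outcome_system = character(),
    outcome_code = character(), hpo = character(), negated = logical()))
  s0 <- map_statistics(empty)
  expect_equal(s0$n_entries, 0L)
  expect_equal(s0$n_hpo, 0L)
  expect_equal(s0$mean_loinc_per_hpo, 0)
})
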