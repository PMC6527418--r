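# Synthetic fixtures and cohorts with known ground truth. The generator
# emulates a de-identified EHR extract: patients with encounter dates,
# LOINC-coded quantitative lab results with reference ranges (or
# interpretation codes), prednisone prescription counts, asthma diagnosis
# codes, and per-phenotype presence drawn from a logistic model with planted
# log-odds effects for the two exposures. Everything is driven by one seed.

# -- mini ontology ------------------------------------------------------------

mini_hpo_terms <- function() {
  tribble_terms <- list(
    c("HP:0000001", "All", NA),
    c("HP:0000118", "Phenotypic abnormality", "HP:0000001"),
    c("HP:0001871", "Abnormality of blood and blood-forming tissues", "HP:0000118"),
    c("HP:0001879", "Abnormal eosinophil morphology", "HP:0001871"),
    c("HP:0020064", "Abnormal eosinophil count", "HP:0001879"),
    c("HP:0001880", "Eosinophilia", "HP:0020064"),
    c("HP:0020059", "Increased red blood cell count", "HP:0001871"),
    c("HP:0001974", "Leukocytosis", "HP:0001871"),
    c("HP:0011897", "Neutrophilia", "HP:0001974"),
    c("HP:0012311", "Monocytosis", "HP:0001871"),
    c("HP:0032245", "Abnormal metabolism", "HP:0000118"),
    c("HP:0100508", "Abnormality of vitamin metabolism", "HP:0032245"),
    c("HP:0040087", "Increased blood folate concentration", "HP:0100508"),
    c("HP:0200502", "Vitamin B12 deficiency", "HP:0100508"),
    c("HP:0012053", "Decreased serum calciferol", "HP:0100508"),
    c("HP:0012052", "Decreased serum calcitriol", "HP:0100508"),
    c("HP:0011014", "Abnormal glucose homeostasis", "HP:0032245"),
    c("HP:0003074", "Hyperglycemia", "HP:0011014"),
    c("HP:0001943", "Hypoglycemia", "HP:0011014"),
    c("HP:0011042", "Abnormal blood potassium concentration", "HP:0032245"),
    c("HP:0002153", "Hyperkalemia", "HP:0011042"),
    c("HP:0002900", "Hypokalemia", "HP:0011042"),
    c("HP:0003073", "Hypoalbuminemia", "HP:0032245"),
    c("HP:0003236", "Elevated circulating creatine kinase concentration", "HP:0032245"),
    c("HP:0003362", "Increased VLDL cholesterol concentration", "HP:0032245"),
    c("HP:0000079", "Abnormality of the urinary system", "HP:0000118"),
    c("HP:0012086", "Abnormal urinary color", "HP:0000079"),
    c("HP:0040318", "Red urine", "HP:0012086"),
    c("HP:0040319", "Dark urine", "HP:0012086"),
    c("HP:0031812", "Nitrituria", "HP:0000079")
  )
  tibble(
    id = map_chr(tribble_terms, 1),
    label = map_chr(tribble_terms, 2),
    parent = map_chr(tribble_terms, 3)
  )
}

#' Write the bundled mini ontology fixture
#'
#' A ~30-term abnormal-phenotype ontology (blood, metabolism, urinary
#' branches) sufficient to exercise every conversion and propagation path:
#' the eosinophilia ancestor chain, the vitamin-metabolism subtree whose
#' sibling children aggregate to a common parent, the potassium and glucose
#' terms, and the urinary-color nominal outcomes. Both OBO 1.2 and
#' obographs-JSON serializations are written; output bytes are deterministic.
#'
#' @param path Output path; with extension `.obo` or `.json` that single
#'   format is written, otherwise both `<path>.obo` and `<path>.json`.
#' @return Paths of the written files, invisibly.
#' @export
make_fixture_ontology <- function(path) {
  tt <- mini_hpo_terms()
  write_obo <- function(p) {
    header <- c("format-version: 1.2", "ontology: mini-hpo-fixture", "")
    stanzas <- unlist(lapply(seq_len(nrow(tt)), function(i) {
      s <- c("[Term]", paste0("id: ", tt$id[i]), paste0("name: ", tt$label[i]))
      if (!is.na(tt$parent[i])) {
        lbl <- tt$label[match(tt$parent[i], tt$id)]
        s <- c(s, paste0("is_a: ", tt$parent[i], " ! ", lbl))
      }
      c(s, "")
    }))
    readr::write_lines(c(header, stanzas), p)
    p
  }
  write_json <- function(p) {
    uri <- function(id) paste0("http://purl.obolibrary.org/obo/",
                               sub(":", "_", id))
    nodes <- lapply(seq_len(nrow(tt)), function(i) {
      list(id = uri(tt$id[i]), lbl = tt$label[i])
    })
    e <- tt[!is.na(tt$parent), ]
    edges <- lapply(seq_len(nrow(e)), function(i) {
      list(sub = uri(e$id[i]), pred = "is_a", obj = uri(e$parent[i]))
    })
    doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
    jsonlite::write_json(doc, p, auto_unbox = TRUE, pretty = FALSE)
    p
  }
  out <- if (grepl("\\.obo$", path)) {
    write_obo(path)
  } else if (grepl("\\.json$", path)) {
    write_json(path)
  } else {
    c(write_obo(paste0(path, ".obo")), write_json(paste0(path, ".json")))
  }
  invisible(out)
}

# -- panel and effects --------------------------------------------------------

#' Default synthetic LOINC panel
#'
#' Quantitative tests in the reserved synthetic 9xxxx LOINC space, one per
#' effect phenotype, each with a normal reference range and the direction in
#' which an abnormal result lies.
#'
#' @return Tibble `term`, `loinc`, `direction` (`"high"`/`"low"`), `low`,
#'   `high`, `unit`.
#' @export
default_panel <- function() {
  tibble(
    term = c("HP:0001880", "HP:0020059", "HP:0003073", "HP:0002900",
             "HP:0040087", "HP:0012053", "HP:0003074"),
    loinc = c("90001-1", "90002-2", "90003-3", "90004-4",
              "90005-5", "90006-6", "90007-7"),
    direction = c("high", "high", "low", "low", "high", "low", "high"),
    low = c(0, 3.9, 3.5, 3.5, 2.7, 30, 70),
    high = c(0.5, 5.2, 5.0, 5.1, 17, 100, 100),
    unit = c("10*3/uL", "10*6/uL", "g/dL", "mmol/L", "ng/mL", "ng/mL", "mg/dL")
  )
}

#' Default planted phenotype effects
#'
#' Baseline prevalences and planted log odds ratios for the two exposures,
#' chosen to mirror the kinds of effects the screen is meant to detect:
#' strong prednisone effects on blood phenotypes, modest asthma effects on
#' eosinophilia and the vitamin-metabolism children, and one null phenotype.
#'
#' @return Tibble `term`, `baseline_prevalence`, `log_or_prednisone`,
#'   `log_or_asthma`.
#' @export
default_effects <- function() {
  tibble(
    term = c("HP:0001880", "HP:0020059", "HP:0003073", "HP:0002900",
             "HP:0040087", "HP:0012053", "HP:0003074"),
    baseline_prevalence = c(0.15, 0.10, 0.12, 0.10, 0.03, 0.05, 0.20),
    log_or_prednisone = c(log(3.74), log(2.48), log(2), log(2), 0, 0, 0),
    log_or_asthma = c(log(1.17), log(1.5), 0, 0, log(1.7), log(1.7), 0)
  )
}

#' Write the fixture annotation map
#'
#' Covers every mapping pattern: the quantitative potassium test
#' (L/N/H/A), the ordinal urine-nitrite test (POS/NEG with negation), the
#' nominal urine-color test with external SNOMED-CT-style outcome codes, the
#' three glucose tests rolled up to one hyperglycemia term, and the
#' synthetic quantitative panel used by the cohort generator.
#'
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
make_fixture_annotations <- function(path) {
  write_annotation_tsv(default_annotation_map(), path)
  invisible(path)
}

fixture_annotation_tbl <- function() {
  snomed <- "http://snomed.info/sct"
  fixed <- dplyr::tribble(
    ~loinc, ~scale, ~outcome_system, ~outcome_code, ~hpo, ~negated,
    "6298-4", "Qn", FHIR_SYSTEM, "L", "HP:0002900", FALSE,
    "6298-4", "Qn", FHIR_SYSTEM, "H", "HP:0002153", FALSE,
    "6298-4", "Qn", FHIR_SYSTEM, "N", "HP:0011042", TRUE,
    "6298-4", "Qn", FHIR_SYSTEM, "A", "HP:0011042", FALSE,
    "32710-6", "Ord", FHIR_SYSTEM, "POS", "HP:0031812", FALSE,
    "32710-6", "Ord", FHIR_SYSTEM, "NEG", "HP:0031812", TRUE,
    "5778-6", "Nom", snomed, "371240000", "HP:0040318", FALSE,
    "5778-6", "Nom", snomed, "373067005", "HP:0040319", FALSE,
    "15074-8", "Qn", FHIR_SYSTEM, "H", "HP:0003074", FALSE,
    "15074-8", "Qn", FHIR_SYSTEM, "L", "HP:0001943", FALSE,
    "15074-8", "Qn", FHIR_SYSTEM, "N", "HP:0011014", TRUE,
    "2339-0", "Qn", FHIR_SYSTEM, "H", "HP:0003074", FALSE,
    "2339-0", "Qn", FHIR_SYSTEM, "L", "HP:0001943", FALSE,
    "2339-0", "Qn", FHIR_SYSTEM, "N", "HP:0011014", TRUE,
    "2345-7", "Qn", FHIR_SYSTEM, "H", "HP:0003074", FALSE,
    "2345-7", "Qn", FHIR_SYSTEM, "L", "HP:0001943", FALSE,
    "2345-7", "Qn", FHIR_SYSTEM, "N", "HP:0011014", TRUE
  )
  panel <- default_panel()
  abn_code <- ifelse(panel$direction == "high", "H", "L")
  panel_rows <- bind_rows(
    tibble(loinc = panel$loinc, scale = "Qn", outcome_system = FHIR_SYSTEM,
           outcome_code = abn_code, hpo = panel$term, negated = FALSE),
    tibble(loinc = panel$loinc, scale = "Qn", outcome_system = FHIR_SYSTEM,
           outcome_code = "N", hpo = panel$term, negated = TRUE)
  )
  bind_rows(fixed, panel_rows) |>
    mutate(curator = "fixture", created_on = "2024-01-01")
}

#' The worked-example bundle: four high-glucose observations
#'
#' One patient with LOINC 15074-8 performed twice and 2339-0 and 2345-7 once
#' each, every result abnormally high, so all four observations convert to
#' Hyperglycemia (HP:0003074).
#'
#' @return A FHIR Bundle as a list.
#' @export
fig3_bundle <- function() {
  mk <- function(id, loinc, value, date) {
    list(
      resourceType = "Observation", id = id,
      subject = list(reference = "Patient/example-patient"),
      code = list(coding = list(list(system = "http://loinc.org", code = loinc))),
      effectiveDateTime = date,
      valueQuantity = list(value = value, unit = "mg/dL"),
      referenceRange = list(list(low = list(value = 70, unit = "mg/dL"),
                                 high = list(value = 100, unit = "mg/dL")))
    )
  }
  list(resourceType = "Bundle", type = "collection", entry = list(
    list(resource = mk("glucose-1", "15074-8", 180, "2019-01-05T08:30:00")),
    list(resource = mk("glucose-2", "2339-0", 195, "2019-02-01T09:00:00")),
    list(resource = mk("glucose-3", "15074-8", 172, "2019-03-10T08:45:00")),
    list(resource = mk("glucose-4", "2345-7", 210, "2019-04-20T10:15:00"))
  ))
}

# -- generative spec ----------------------------------------------------------

#' Generative specification for a synthetic cohort
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed fixing all randomness.
#' @param loinc_panel As [default_panel()].
#' @param phenotype_effects As [default_effects()].
#' @param p_asthma Prevalence of an acute asthma diagnosis (default 1/3).
#' @param p_prednisone_given_asthma,p_prednisone_given_other Probability of
#'   being a frequent prednisone user conditional on asthma status (defaults
#'   0.142 / 0.085).
#' @param mean_encounter_days Poisson mean of distinct encounter days for
#'   regular patients (default 24).
#' @param low_visit_fraction Fraction of patients with fewer than ten
#'   encounter days, exercising the exclusion rule (default 0.05).
#' @param interpretation_only_fraction Fraction of observations emitted with
#'   an interpretation code and no value, exercising the code path of the
#'   conversion algorithm (default 0.3).
#' @param unmapped_loinc_fraction Expected fraction of observations carrying
#'   a LOINC code with no annotation (default 0.1; must be < 0.5).
#' @return A list of class `generative_spec`.
#' @export
generative_spec <- function(n_patients = 2000L, seed = 1L,
                            loinc_panel = default_panel(),
                            phenotype_effects = default_effects(),
                            p_asthma = 1 / 3,
                            p_prednisone_given_asthma = 0.142,
                            p_prednisone_given_other = 0.085,
                            mean_encounter_days = 24,
                            low_visit_fraction = 0.05,
                            interpretation_only_fraction = 0.3,
                            unmapped_loinc_fraction = 0.1) {
  if (n_patients < 1) stopf("n_patients must be >= 1", class = "phelab_spec_error")
  fr <- c(p_asthma, p_prednisone_given_asthma, p_prednisone_given_other,
          low_visit_fraction, interpretation_only_fraction,
          unmapped_loinc_fraction)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]",
                                  class = "phelab_spec_error")
  if (unmapped_loinc_fraction >= 0.5) {
    stopf("unmapped_loinc_fraction must be < 0.5", class = "phelab_spec_error")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    loinc_panel = loinc_panel, phenotype_effects = phenotype_effects,
    p_asthma = p_asthma,
    p_prednisone_given_asthma = p_prednisone_given_asthma,
    p_prednisone_given_other = p_prednisone_given_other,
    mean_encounter_days = mean_encounter_days,
    low_visit_fraction = low_visit_fraction,
    interpretation_only_fraction = interpretation_only_fraction,
    unmapped_loinc_fraction = unmapped_loinc_fraction
  ), class = "generative_spec")
}

#' The annotation map used by the synthetic generator
#'
#' @return The fixture [annotation_map()], built in memory.
#' @export
default_annotation_map <- function() {
  annotation_map(fixture_annotation_tbl())
}

#' The mini ontology used by the synthetic generator
#'
#' @return The fixture ontology, built in memory.
#' @export
default_ontology <- function() {
  tt <- mini_hpo_terms()
  e <- tt[!is.na(tt$parent), c("id", "parent")]
  ontology(terms = tibble(id = tt$id, label = tt$label),
           edges = tibble(child = e$id, parent = e$parent))
}

# -- cohort generation --------------------------------------------------------

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-patient exposures and encounter histories, per-term phenotype
#' presence from the planted logistic model, and the corresponding
#' observations: a patient intended PRESENT receives at least three abnormal
#' quantitative results of the term's panel LOINC (values outside the normal
#' range, or an `H`/`L` interpretation code for the value-free fraction); a
#' patient intended absent receives normal results only. Extra observations
#' with unannotated LOINC codes are interleaved at the configured rate. All
#' randomness comes from `spec$seed`; the same spec yields byte-identical
#' outputs.
#'
#' @param spec A [generative_spec()].
#' @param out_dir Optional directory; when given, writes
#'   `observations.ndjson` (one FHIR Observation per line), `patients.csv`,
#'   `encounters.csv`, `medications.csv`, `diagnoses.csv`,
#'   `annotations.tsv`, `ontology.obo`, `ground_truth.json`, and
#'   `spec.json`.
#' @return A list with `observations` (parsed-observation tibble),
#'   `patients`, `encounters`, `medications`, `diagnoses` (extract tibbles),
#'   `ground_truth` (list: `exposures`, `presence`, `effects`), and `files`
#'   (written paths or `NULL`).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "generative_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  pid <- sprintf("P%05d", seq_len(n))

  asthma <- rbinom(n, 1, spec$p_asthma) == 1
  p_pred <- ifelse(asthma, spec$p_prednisone_given_asthma,
                   spec$p_prednisone_given_other)
  frequent <- rbinom(n, 1, p_pred) == 1
  rx_count <- ifelse(frequent, 4L + rpois(n, 2), sample(0:3, n, replace = TRUE))

  all_days <- seq(as.Date("2004-01-01"), as.Date("2016-12-31"), by = "day")
  low_visit <- runif(n) < spec$low_visit_fraction
  n_days <- ifelse(low_visit, sample(3:9, n, replace = TRUE),
                   pmax(10L, rpois(n, spec$mean_encounter_days)))
  enc <- tibble(patient_id = rep(pid, n_days),
                date = as.Date(unlist(lapply(n_days, function(k) {
                  sort(sample(all_days, k))
                }), use.names = FALSE), origin = "1970-01-01"))

  eff <- spec$phenotype_effects
  grid <- tidyr::expand_grid(i = seq_len(n), j = seq_len(nrow(eff)))
  lin <- qlogis(eff$baseline_prevalence[grid$j]) +
    eff$log_or_prednisone[grid$j] * frequent[grid$i] +
    eff$log_or_asthma[grid$j] * asthma[grid$i]
  grid$present <- rbinom(nrow(grid), 1, plogis(lin)) == 1

  panel <- left_join(eff["term"], spec$loinc_panel, by = "term")
  if (anyNA(panel$loinc)) {
    stopf("every effect term needs a LOINC panel entry",
          class = "phelab_spec_error")
  }
  grid$n_obs <- ifelse(grid$present, 3L + rpois(nrow(grid), 1),
                       1L + rpois(nrow(grid), 1))
  obs <- grid |>
    mutate(patient_id = pid[.data$i]) |>
    tidyr::uncount(.data$n_obs)
  k <- nrow(obs)
  dir <- panel$direction[obs$j]
  lo <- panel$low[obs$j]; hi <- panel$high[obs$j]
  w <- hi - lo
  abnormal <- obs$present
  value <- ifelse(abnormal,
                  ifelse(dir == "high", runif(k, hi, hi + 0.5 * w),
                         runif(k, lo - 0.5 * w, lo)),
                  runif(k, lo, hi))
  interp_only <- runif(k) < spec$interpretation_only_fraction
  interp_code <- ifelse(abnormal, ifelse(dir == "high", "H", "L"), "N")

  # observation dates drawn from the patient's encounter days
  offsets <- c(0L, cumsum(n_days))
  flat_dates <- enc$date
  idx <- offsets[obs$i] + floor(runif(k) * n_days[obs$i]) + 1L
  obs_date <- flat_dates[idx]
  obs_time <- paste0(format(obs_date), "T",
                     sprintf("%02d:%02d:00", sample(7:18, k, replace = TRUE),
                             sample(0:59, k, replace = TRUE)))

  range_tbl <- function(l, h, u) tibble(low = l, high = h, low_unit = u,
                                        high_unit = u, qualified = FALSE)
  empty_rng <- tibble(low = double(), high = double(), low_unit = character(),
                      high_unit = character(), qualified = logical())
  panel_ranges <- lapply(seq_len(nrow(panel)), function(j) {
    range_tbl(panel$low[j], panel$high[j], panel$unit[j])
  })

  mapped <- tibble(
    subject_id = obs$patient_id,
    loinc = panel$loinc[obs$j],
    effective_time = obs_time,
    value_type = ifelse(interp_only, "missing", "numeric"),
    value_num = ifelse(interp_only, NA_real_, round(value, 2)),
    value_unit = ifelse(interp_only, NA_character_, panel$unit[obs$j]),
    value_system = NA_character_, value_code = NA_character_,
    value_text = NA_character_,
    interpretation_raw = ifelse(interp_only, interp_code, NA_character_),
    ranges = {
      r <- panel_ranges[obs$j]
      r[interp_only] <- list(empty_rng)
      r
    }
  )

  # unannotated-LOINC companions at rate u/(1-u) per mapped observation,
  # so the expected unmapped share of all observations is u
  u <- spec$unmapped_loinc_fraction
  spawn <- if (u > 0) runif(k) < u / (1 - u) else rep(FALSE, k)
  if (any(spawn)) {
    ku <- sum(spawn)
    unmapped <- tibble(
      subject_id = mapped$subject_id[spawn],
      loinc = sample(c("99991-1", "99992-2", "99993-3"), ku, replace = TRUE),
      effective_time = mapped$effective_time[spawn],
      value_type = "numeric",
      value_num = round(runif(ku, 0, 10), 2),
      value_unit = "U/L", value_system = NA_character_,
      value_code = NA_character_, value_text = NA_character_,
      interpretation_raw = NA_character_,
      ranges = list(range_tbl(2, 8, "U/L"))
    )
    observations <- bind_rows(mapped, unmapped)
  } else {
    observations <- mapped
  }
  observations <- observations |>
    arrange(.data$subject_id, .data$effective_time, .data$loinc) |>
    mutate(obs_id = sprintf("O%07d", row_number()), .before = 1)

  patients <- tibble(
    patient_id = pid,
    sex = ifelse(runif(n) < 0.589, "F", "M"),
    birth_date = as.Date("1930-01-01") + sample.int(22000, n, replace = TRUE)
  )
  med_dates <- lapply(seq_len(n), function(i) {
    d <- flat_dates[(offsets[i] + 1L):offsets[i + 1L]]
    d[sample.int(length(d), rx_count[i], replace = TRUE)]
  })
  # medication and diagnosis dates fall on encounter days
  first_enc <- flat_dates[offsets[seq_len(n)] + 1L]
  medications <- tibble(
    patient_id = rep(pid, rx_count),
    date = as.Date(unlist(med_dates, use.names = FALSE), origin = "1970-01-01"),
    drug_name = "prednisone"
  ) |>
    bind_rows(tibble(patient_id = pid, date = first_enc,
                     drug_name = "albuterol"))
  diagnoses <- bind_rows(
    tibble(patient_id = pid[asthma], date = first_enc[asthma],
           icd_version = "10", code = "J45.909"),
    tibble(patient_id = pid, date = first_enc, icd_version = "10",
           code = "R05")
  ) |> arrange(.data$patient_id, .data$code)

  ground_truth <- list(
    exposures = tibble(patient_id = pid, frequent_prednisone = frequent,
                       acute_asthma = asthma,
                       prednisone_rx_count = rx_count),
    presence = tibble(patient_id = pid[grid$i], term = eff$term[grid$j],
                      present = grid$present),
    effects = eff
  )

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ndjson <- file.path(out_dir, "observations.ndjson")
    lines <- vapply(seq_len(nrow(observations)), function(i) {
      as.character(jsonlite::toJSON(observation_to_fhir(observations[i, ]),
                                    auto_unbox = TRUE, digits = NA))
    }, character(1))
    readr::write_lines(lines, ndjson)
    readr::write_csv(patients, file.path(out_dir, "patients.csv"), progress = FALSE)
    readr::write_csv(enc, file.path(out_dir, "encounters.csv"), progress = FALSE)
    readr::write_csv(medications, file.path(out_dir, "medications.csv"),
                     progress = FALSE)
    readr::write_csv(diagnoses, file.path(out_dir, "diagnoses.csv"),
                     progress = FALSE)
    make_fixture_annotations(file.path(out_dir, "annotations.tsv"))
    make_fixture_ontology(file.path(out_dir, "ontology.obo"))
    jsonlite::write_json(
      list(exposures = ground_truth$exposures,
           presence = ground_truth$presence, effects = eff),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    spec_plain <- unclass(spec)
    jsonlite::write_json(spec_plain[setdiff(names(spec_plain),
                                            c("loinc_panel", "phenotype_effects"))],
                         file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(out_dir, full.names = TRUE)
  }

  list(observations = observations, patients = patients, encounters = enc,
       medications = medications, diagnoses = diagnoses,
       ground_truth = ground_truth, files = files)
}

# -- direct association harness ----------------------------------------------

#' Build profile rows from intended presence
#'
#' Turns a ground-truth presence table into the minimal
#' [build_profiles()]-shaped tibble the association screen consumes: each
#' present (patient, term) pair gets `min_obs_for_present` observations, and
#' absent pairs get no row (hence ABSENT).
#'
#' @param presence Tibble `patient_id`, `term`, `present` (logical).
#' @param cfg An [analysis_config()].
#' @return A `patient_profiles` tibble.
#' @export
profiles_from_presence <- function(presence, cfg = analysis_config()) {
  pres <- filter(presence, .data$present)
  out <- tibble(
    patient_id = pres$patient_id, term = pres$term, negated = FALSE,
    asserted_count = cfg$min_obs_for_present,
    propagated_count = cfg$min_obs_for_present,
    n_loinc = 1L, first_time = NA_character_, last_time = NA_character_,
    presence = "PRESENT"
  )
  class(out) <- c("patient_profiles", class(tibble()))
  attr(out, "config") <- cfg
  out
}

#' Simulate a presence/exposure cohort directly from the logistic model
#'
#' The parameter-recovery harness: draws exposures and per-term presence
#' from known log odds ratios without going through FHIR emission, so the
#' statistical properties of the screen can be measured cheaply.
#'
#' @param n_patients Number of patients.
#' @param effects Tibble `term`, `baseline_prevalence`, `log_or_prednisone`,
#'   `log_or_asthma`.
#' @param seed Integer seed.
#' @param p_prednisone,p_asthma Marginal exposure prevalences.
#' @return A list with `profiles`, `exposures`, `effects`.
#' @export
simulate_association_cohort <- function(n_patients, effects, seed,
                                        p_prednisone = 0.104,
                                        p_asthma = 1 / 3) {
  set.seed(seed)
  pid <- sprintf("S%06d", seq_len(n_patients))
  pred <- rbinom(n_patients, 1, p_prednisone) == 1
  asthma <- rbinom(n_patients, 1, p_asthma) == 1
  grid <- tidyr::expand_grid(i = seq_len(n_patients), j = seq_len(nrow(effects)))
  lin <- qlogis(effects$baseline_prevalence[grid$j]) +
    effects$log_or_prednisone[grid$j] * pred[grid$i] +
    effects$log_or_asthma[grid$j] * asthma[grid$i]
  present <- rbinom(nrow(grid), 1, plogis(lin)) == 1
  presence <- tibble(patient_id = pid[grid$i], term = effects$term[grid$j],
                     present = present)
  list(
    profiles = profiles_from_presence(presence),
    exposures = tibble(patient_id = pid, frequent_prednisone = pred,
                       acute_asthma = asthma),
    effects = effects
  )
}
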