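# Per-patient phenotype profiles and cohort bookkeeping: observation-count
# thresholds for calling a phenotype present, encounter-day exclusions, and
# binary exposure flags (frequent prednisone use, acute asthma diagnosis).

#' Analysis configuration
#'
#' Bundles the thresholds of the cohort analysis:
#' * `min_obs_for_present` — observations of an abnormality required to call
#'   the phenotype PRESENT (default 3: an isolated abnormal measurement may
#'   be an artifact);
#' * `min_encounter_days` — patients with medical encounters on fewer
#'   distinct days are excluded (default 10);
#' * `prednisone_rx_threshold` — strictly more prescriptions than this makes
#'   a frequent user (default 3, i.e. >3);
#' * `uniformity_threshold` — terms whose PRESENT/ABSENT split is at least
#'   this uniform across the cohort are excluded from association analysis
#'   (default 0.95);
#' * `min_patients_per_term` — minimum number of patients carrying the
#'   phenotype for it to be analyzable (default 100);
#' * `ci_z` — multiplier on the standard error for confidence intervals
#'   (default 1.98);
#' * `asthma_codes` — ICD-9/10 code prefixes defining an acute asthma
#'   diagnosis, matched prefix-wise after dot-stripping (default `J45`/`493`);
#' * `propagate_before_threshold` — apply the presence threshold to
#'   propagated counts (default `TRUE`; this is what lets three observations
#'   spread over sibling terms make the parent PRESENT), switchable for
#'   sensitivity analysis;
#' * `stop_set` — terms excluded from propagation.
#'
#' @param min_obs_for_present,min_encounter_days,prednisone_rx_threshold
#'   Positive integers.
#' @param uniformity_threshold Fraction in (0.5, 1].
#' @param min_patients_per_term Positive integer.
#' @param ci_z Positive numeric.
#' @param asthma_codes Character vector of ICD code prefixes.
#' @param propagate_before_threshold Logical.
#' @param stop_set Character vector of term ids.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_obs_for_present = 3L,
                            min_encounter_days = 10L,
                            prednisone_rx_threshold = 3L,
                            uniformity_threshold = 0.95,
                            min_patients_per_term = 100L,
                            ci_z = 1.98,
                            asthma_codes = c("J45", "493"),
                            propagate_before_threshold = TRUE,
                            stop_set = DEFAULT_STOP_SET) {
  stopifnot(min_obs_for_present >= 1, min_encounter_days >= 1,
            prednisone_rx_threshold >= 1, ci_z > 0, min_patients_per_term >= 1,
            uniformity_threshold > 0.5, uniformity_threshold <= 1)
  structure(list(
    min_obs_for_present = as.integer(min_obs_for_present),
    min_encounter_days = as.integer(min_encounter_days),
    prednisone_rx_threshold = as.integer(prednisone_rx_threshold),
    uniformity_threshold = uniformity_threshold,
    min_patients_per_term = as.integer(min_patients_per_term),
    ci_z = ci_z,
    asthma_codes = asthma_codes,
    propagate_before_threshold = propagate_before_threshold,
    stop_set = stop_set
  ), class = "analysis_config")
}

#' Build per-patient phenotype profiles from calls
#'
#' Groups calls by patient, term, and negation; counts observations and
#' records first/last observation times and the number of distinct LOINC
#' tests contributing; propagates non-negated counts up the ontology; and
#' assigns three-state presence: `PRESENT` when the (propagated) count
#' reaches `min_obs_for_present`, `INDETERMINATE` for a lower positive
#' count, and — implicitly, for terms not in a patient's profile — `ABSENT`:
#' a patient is classified as not having a phenotype only when the term was
#' never assigned. Negated (normal-result) calls are retained as asserted
#' rows with `presence = NA`; they never propagate and never count toward
#' presence.
#'
#' @param calls Calls tibble from [convert_collection()] (`subject_id`,
#'   `hpo`, `negated`, `loinc`, `time`, `obs_id`).
#' @param ont An [ontology()] object.
#' @param cfg An [analysis_config()].
#' @return A tibble of class `patient_profiles`: `patient_id`, `term`,
#'   `negated`, `asserted_count`, `propagated_count`, `n_loinc`,
#'   `first_time`, `last_time`, `presence`.
#' @export
build_profiles <- function(calls, ont, cfg = analysis_config()) {
  if (nrow(calls) == 0) {
    out <- tibble(patient_id = character(), term = character(),
                  negated = logical(), asserted_count = integer(),
                  propagated_count = integer(), n_loinc = integer(),
                  first_time = character(), last_time = character(),
                  presence = character())
    class(out) <- c("patient_profiles", class(out))
    attr(out, "config") <- cfg
    return(out)
  }
  asserted <- calls |>
    group_by(patient_id = .data$subject_id, term = .data$hpo, .data$negated) |>
    summarise(asserted_count = n(),
              n_loinc = n_distinct(.data$loinc),
              first_time = if (all(is.na(.data$time))) NA_character_ else
                min(.data$time, na.rm = TRUE),
              last_time = if (all(is.na(.data$time))) NA_character_ else
                max(.data$time, na.rm = TRUE),
              .groups = "drop")

  # ancestor closure per distinct non-negated term, then one join
  abn_terms <- unique(asserted$term[!asserted$negated])
  known <- abn_terms[vapply(abn_terms, function(t) !is.na(resolve_term(ont, t)),
                            logical(1))]
  anc_tbl <- purrr::map_dfr(known, function(t) {
    tibble(term = t, target = c(t, ancestors(ont, t, cfg$stop_set)))
  })
  unknown_self <- tibble(term = setdiff(abn_terms, known),
                         target = setdiff(abn_terms, known))
  anc_tbl <- bind_rows(anc_tbl, unknown_self)

  propagated <- asserted |>
    filter(!.data$negated) |>
    inner_join(anc_tbl, by = "term", relationship = "many-to-many") |>
    group_by(.data$patient_id, term = .data$target) |>
    summarise(propagated_count = sum(.data$asserted_count), .groups = "drop") |>
    mutate(negated = FALSE)

  out <- asserted |>
    dplyr::full_join(propagated, by = c("patient_id", "term", "negated")) |>
    mutate(
      asserted_count = coalesce(.data$asserted_count, 0L),
      propagated_count = if_else(.data$negated, NA_integer_,
                                 as.integer(coalesce(.data$propagated_count, 0L))),
      n_loinc = coalesce(.data$n_loinc, 0L)
    )
  presence_basis <- if (cfg$propagate_before_threshold) {
    out$propagated_count
  } else {
    out$asserted_count
  }
  out$presence <- case_when(
    out$negated ~ NA_character_,
    presence_basis >= cfg$min_obs_for_present ~ "PRESENT",
    presence_basis >= 1 ~ "INDETERMINATE",
    TRUE ~ "ABSENT"
  )
  out <- arrange(out, .data$patient_id, .data$term, .data$negated)
  class(out) <- c("patient_profiles", class(tibble()))
  attr(out, "config") <- cfg
  out
}

#' Aggregate calls per patient and term
#'
#' The per-patient display aggregate: for each (patient, HPO term, negation)
#' the number of source observations, the number of distinct LOINC tests, and
#' the dates of the first and last observation.
#'
#' @param calls Calls tibble from [convert_collection()].
#' @param ont Optional ontology used to attach term labels.
#' @return A tibble sorted by patient and descending observation count.
#' @export
aggregate_calls <- function(calls, ont = NULL) {
  out <- calls |>
    group_by(patient_id = .data$subject_id, term = .data$hpo, .data$negated) |>
    summarise(n_observations = n(),
              n_loinc = n_distinct(.data$loinc),
              first_time = if (all(is.na(.data$time))) NA_character_ else
                min(.data$time, na.rm = TRUE),
              last_time = if (all(is.na(.data$time))) NA_character_ else
                max(.data$time, na.rm = TRUE),
              .groups = "drop") |>
    arrange(.data$patient_id, dplyr::desc(.data$n_observations), .data$term)
  if (!is.null(ont)) {
    out <- mutate(out, label = term_label(ont, .data$term),
                  .after = "term")
  }
  out
}

#' Assemble patient records from cohort extract tables
#'
#' @param patients Tibble `patient_id`, optionally `sex`, `birth_date`.
#' @param encounters Tibble `patient_id`, `date`.
#' @param medications Tibble `patient_id`, `date`, `drug_name`.
#' @param diagnoses Tibble `patient_id`, `date`, `icd_version`, `code`.
#' @param cfg An [analysis_config()].
#' @return Tibble `patient_id`, `sex`, `birth_date`, `n_encounter_days`
#'   (distinct calendar dates across all record types),
#'   `prednisone_rx_count`, `dx_codes` (list-column).
#' @export
build_patient_records <- function(patients, encounters, medications, diagnoses,
                                  cfg = analysis_config()) {
  dates <- bind_rows(
    select(encounters, "patient_id", "date"),
    select(medications, "patient_id", "date"),
    select(diagnoses, "patient_id", "date")
  ) |>
    filter(!is.na(.data$date)) |>
    distinct(.data$patient_id, .data$date) |>
    group_by(.data$patient_id) |>
    summarise(n_encounter_days = n(), .groups = "drop")
  rx <- medications |>
    filter(grepl("prednisone", .data$drug_name, ignore.case = TRUE)) |>
    group_by(.data$patient_id) |>
    summarise(prednisone_rx_count = n(), .groups = "drop")
  dx <- diagnoses |>
    group_by(.data$patient_id) |>
    summarise(dx_codes = list(unique(.data$code)), .groups = "drop")
  patients |>
    left_join(dates, by = "patient_id") |>
    left_join(rx, by = "patient_id") |>
    left_join(dx, by = "patient_id") |>
    mutate(n_encounter_days = coalesce(.data$n_encounter_days, 0L),
           prednisone_rx_count = coalesce(.data$prednisone_rx_count, 0L),
           dx_codes = purrr::map(.data$dx_codes, function(x) x %||% character()))
}

#' Apply cohort exclusions
#'
#' Patients who rarely visit receive few laboratory tests and therefore few
#' phenotypes; those with medical encounters on fewer than
#' `min_encounter_days` distinct days are excluded.
#'
#' @param records Tibble from [build_patient_records()].
#' @param cfg An [analysis_config()].
#' @return `records` with added `retained` (logical) and `exclusion_reason`.
#' @export
apply_exclusions <- function(records, cfg = analysis_config()) {
  records |>
    mutate(retained = .data$n_encounter_days >= cfg$min_encounter_days,
           exclusion_reason = if_else(.data$retained, NA_character_,
                                      "FEW_ENCOUNTER_DAYS"))
}

#' Flag binary exposures
#'
#' `frequent_prednisone` is strictly more than `prednisone_rx_threshold`
#' prescriptions; `acute_asthma` is any diagnosis code matching an entry of
#' `asthma_codes` as a prefix after stripping dots from both sides.
#'
#' @param records Tibble from [build_patient_records()].
#' @param cfg An [analysis_config()].
#' @return Tibble `patient_id`, `frequent_prednisone`, `acute_asthma`.
#' @export
flag_exposures <- function(records, cfg = analysis_config()) {
  prefixes <- gsub(".", "", cfg$asthma_codes, fixed = TRUE)
  match_asthma <- function(codes) {
    if (length(codes) == 0) return(FALSE)
    stripped <- gsub(".", "", codes, fixed = TRUE)
    any(vapply(prefixes, function(p) any(startsWith(stripped, p)), logical(1)))
  }
  tibble(
    patient_id = records$patient_id,
    frequent_prednisone = records$prednisone_rx_count > cfg$prednisone_rx_threshold,
    acute_asthma = map_lgl(records$dx_codes, match_asthma)
  )
}

#' Cohort-level profile summary
#'
#' @param profiles A [build_profiles()] result.
#' @param retained Optional character vector of patient ids to restrict to.
#' @return A list of class `profile_summary`: `n_patients`,
#'   `mean_unique_terms` (asserted terms per patient, normal findings
#'   included), `mean_abnormalities` (non-negated asserted terms),
#'   `mean_propagated_terms` (terms with positive propagated count), and
#'   `histogram` (tibble `n_unique_terms`, `n_patients`).
#' @export
profile_summary <- function(profiles, retained = NULL) {
  x <- as_tibble(profiles)
  if (!is.null(retained)) x <- filter(x, .data$patient_id %in% retained)
  if (nrow(x) == 0) {
    out <- list(n_patients = 0L, mean_unique_terms = NA_real_,
                mean_abnormalities = NA_real_, mean_propagated_terms = NA_real_,
                histogram = tibble(n_unique_terms = integer(), n_patients = integer()))
    class(out) <- "profile_summary"
    return(out)
  }
  per_patient <- x |>
    group_by(.data$patient_id) |>
    summarise(
      n_unique = n_distinct(.data$term[.data$asserted_count > 0]),
      n_abn = n_distinct(.data$term[.data$asserted_count > 0 & !.data$negated]),
      n_prop = n_distinct(.data$term[!.data$negated &
                                       coalesce(.data$propagated_count, 0L) > 0]),
      .groups = "drop")
  out <- list(
    n_patients = nrow(per_patient),
    mean_unique_terms = mean(per_patient$n_unique),
    mean_abnormalities = mean(per_patient$n_abn),
    mean_propagated_terms = mean(per_patient$n_prop),
    histogram = per_patient |>
      group_by(n_unique_terms = .data$n_unique) |>
      summarise(n_patients = n(), .groups = "drop")
  )
  class(out) <- "profile_summary"
  out
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n_patients))
  cat(sprintf("  mean unique HPO terms/patient:        %.1f\n", x$mean_unique_terms))
  cat(sprintf("  mean abnormality terms/patient:       %.1f\n", x$mean_abnormalities))
  cat(sprintf("  mean terms/patient after propagation: %.1f\n", x$mean_propagated_terms))
  invisible(x)
}

#' Read cohort extract CSVs from a directory
#'
#' Expects `patients.csv`, `encounters.csv`, `medications.csv`,
#' `diagnoses.csv` with the dialect documented in the package: UTF-8, header
#' rows, ISO dates.
#'
#' @param dir Directory path.
#' @return A named list of tibbles.
#' @export
read_cohort_csvs <- function(dir) {
  read1 <- function(f, types) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stopf("cohort extract file missing: %s", p)
    readr::read_csv(p, col_types = types, progress = FALSE, show_col_types = FALSE)
  }
  list(
    patients = read1("patients.csv", readr::cols(
      patient_id = "c", sex = "c", birth_date = readr::col_date())),
    encounters = read1("encounters.csv", readr::cols(
      patient_id = "c", date = readr::col_date())),
    medications = read1("medications.csv", readr::cols(
      patient_id = "c", date = readr::col_date(), drug_name = "c")),
    diagnoses = read1("diagnoses.csv", readr::cols(
      patient_id = "c", date = readr::col_date(), icd_version = "c", code = "c"))
  )
}
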