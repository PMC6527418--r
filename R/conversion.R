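# Outcome normalization and the LOINC-result -> HPO-term conversion.
#
# A result's outcome is resolved in this order:
#   1. an interpretation code, if present, normalized to a primary code
#      (an explicit "unknown" interpretation fails the record outright);
#   2. for nominal tests (and ordinal tests carrying a coded value) the coded
#      value itself, keyed by its external coding system;
#   3. for quantitative tests, comparison of the numeric value against the
#      normal reference range.
# The resolved outcome key is then looked up in the annotation map.

# secondary -> primary interpretation-code table
.interp_table <- c(
  A = "A", AA = "A", W = "A",
  L = "L", "<" = "L", D = "L", LL = "L", LU = "L",
  N = "N", B = "N", I = "N",
  H = "H", ">" = "H", HH = "H", HU = "H", UH = "H",
  NEG = "NEG", ND = "NEG", NR = "NEG",
  POS = "POS", AC = "POS", DET = "POS", RR = "POS", TOX = "POS", WR = "POS"
)

#' Normalize FHIR interpretation codes to primary outcome codes
#'
#' Total function collapsing the FHIR interpretation-code vocabulary onto the
#' seven primary codes: `A` (abnormal) from `A`, `AA`, `W`; `L` from `L`,
#' `<`, `D`, `LL`, `LU`; `N` from `N`, `B`, `I`; `H` from `H`, `>`, `HH`,
#' `HU`, `UH`; `NEG` from `NEG`, `ND`, `NR`; `POS` from `POS`, `AC`, `DET`,
#' `RR`, `TOX`, `WR`. Every other token — including the literal `"null"` and
#' the quality-control/susceptibility codes — normalizes to `U` (unknown).
#' Matching is case-insensitive after trimming; `<` and `>` are matched
#' literally. The function is idempotent: primary codes map to themselves.
#'
#' @param x Character vector of raw interpretation codes.
#' @return Character vector of primary codes (`A L N H NEG POS U`).
#' @export
#' @examples
#' normalize_interpretation(c("LL", "det", " H ", "SYN-R", "null"))
normalize_interpretation <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- unname(.interp_table[key])
  out[is.na(out)] <- "U"
  out
}

#' Infer the outcome of a quantitative result from its reference range
#'
#' Compares a numeric value with the normal range: below the low bound is
#' `L`, above the high bound is `H`, otherwise `N`. Bounds are inclusive of
#' normal (a value equal to either bound is `N`, the FHIR convention for the
#' normal interval). One-sided ranges compare only the present bound. With no
#' bound at all the result is `NA`, which callers surface as an
#' `INSUFFICIENT_DATA` failure.
#'
#' @param value,low,high Numeric vectors (recycled to common length); `low`
#'   and/or `high` may be `NA`.
#' @return Character vector of `"L"`, `"N"`, `"H"`, or `NA`.
#' @export
#' @examples
#' infer_outcome_from_range(c(3.0, 3.5, 6.1), 3.5, 5.0)
infer_outcome_from_range <- function(value, low, high) {
  n <- max(length(value), length(low), length(high))
  value <- rep_len(value, n); low <- rep_len(low, n); high <- rep_len(high, n)
  dplyr::case_when(
    is.na(low) & is.na(high) ~ NA_character_,
    !is.na(low) & value < low ~ "L",
    !is.na(high) & value > high ~ "H",
    TRUE ~ "N"
  )
}

# pick the range used downstream: first range without an age/population
# qualifier, else the first range
select_range <- function(ranges) {
  if (is.null(ranges) || nrow(ranges) == 0) {
    return(list(low = NA_real_, high = NA_real_,
                low_unit = NA_character_, high_unit = NA_character_))
  }
  i <- which(!ranges$qualified)
  i <- if (length(i) > 0) i[1] else 1L
  list(low = ranges$low[i], high = ranges$high[i],
       low_unit = ranges$low_unit[i], high_unit = ranges$high_unit[i])
}

#' Resolve the outcome key of each observation
#'
#' Applies the precedence rules described above to a tibble of parsed
#' observations, against the scales recorded in the annotation map. No unit
#' conversion is attempted: for range comparison the value's unit and the
#' bound units must be string-equal after trimming, else the record fails
#' with `INSUFFICIENT_DATA` (silent unit coercion is a safety hazard). When a
#' quantitative record carries both a usable interpretation code and a
#' numeric value with a range, the interpretation code wins; if the two
#' disagree the row is flagged in `range_conflict`.
#'
#' @param obs Observations tibble from [parse_bundle()].
#' @param map An [annotation_map()] (source of each LOINC's scale).
#' @return `obs` with added columns `scale`, `outcome_system`,
#'   `outcome_code`, `failure` (`NA` or one of `UNMAPPED_LOINC`,
#'   `UNKNOWN_INTERPRETATION`, `INSUFFICIENT_DATA`), `range_conflict`.
#' @export
resolve_outcomes <- function(obs, map) {
  stopifnot(inherits(map, "annotation_map"))
  scale_tbl <- distinct(as_tibble(map), .data$loinc, .data$scale)
  x <- left_join(obs, scale_tbl, by = "loinc")

  rng <- purrr::map(x$ranges, select_range)
  x$rr_low <- map_dbl(rng, "low")
  x$rr_high <- map_dbl(rng, "high")
  rr_low_unit <- map_chr(rng, "low_unit")
  rr_high_unit <- map_chr(rng, "high_unit")

  trim_na <- function(u) trimws(ifelse(is.na(u), "", u))
  vu <- trim_na(x$value_unit)
  units_ok <- (is.na(x$rr_low) | trim_na(rr_low_unit) == vu) &
    (is.na(x$rr_high) | trim_na(rr_high_unit) == vu)
  usable_range <- (!is.na(x$rr_low) | !is.na(x$rr_high)) & units_ok

  has_interp <- !is.na(x$interpretation_raw) & nzchar(trimws(x$interpretation_raw))
  interp_norm <- ifelse(has_interp, normalize_interpretation(x$interpretation_raw),
                        NA_character_)
  inferred <- ifelse(x$value_type == "numeric" & usable_range,
                     infer_outcome_from_range(x$value_num, x$rr_low, x$rr_high),
                     NA_character_)
  has_coded <- x$value_type == "coded" & !is.na(x$value_code)

  x$failure <- case_when(
    is.na(x$scale) ~ "UNMAPPED_LOINC",
    has_interp & interp_norm == "U" ~ "UNKNOWN_INTERPRETATION",
    has_interp ~ NA_character_,
    x$scale == "Nom" & has_coded ~ NA_character_,
    x$scale == "Ord" & has_coded ~ NA_character_,
    x$scale == "Qn" & x$value_type == "numeric" & !is.na(inferred) ~ NA_character_,
    TRUE ~ "INSUFFICIENT_DATA"
  )
  x$outcome_system <- case_when(
    !is.na(x$failure) ~ NA_character_,
    has_interp ~ FHIR_SYSTEM,
    has_coded ~ x$value_system %na% "",
    TRUE ~ FHIR_SYSTEM
  )
  x$outcome_code <- case_when(
    !is.na(x$failure) ~ NA_character_,
    has_interp ~ interp_norm,
    has_coded ~ x$value_code,
    TRUE ~ inferred
  )
  x$range_conflict <- has_interp & interp_norm %in% c("L", "N", "H") &
    !is.na(inferred) & inferred != interp_norm
  x
}

#' Convert observations into phenotype calls
#'
#' The full per-record conversion: resolve each observation's outcome, look
#' the `(LOINC, outcome)` key up in the annotation map, and emit the HPO term
#' with its negation flag, or a typed failure reason. A resolved `L` or `H`
#' for which no specific entry exists falls back to the LOINC's `A`
#' (abnormal) entry when one is annotated; `N` never falls back to `A`.
#' Conversion is independent per record — permuting the input permutes the
#' output identically.
#'
#' @param obs Observations tibble from [parse_bundle()].
#' @param map An [annotation_map()].
#' @param ont Optional [load_ontology()] result; calls whose HPO id is absent
#'   from the ontology raise a warning.
#' @return `obs` plus columns `scale`, `outcome_system`, `outcome_code`,
#'   `hpo`, `negated`, `range_conflict`, and `status` (`"CONVERTED"` or one
#'   of the failure reasons `UNMAPPED_LOINC`, `UNMAPPED_OUTCOME`,
#'   `UNKNOWN_INTERPRETATION`, `INSUFFICIENT_DATA`). Rows where an
#'   interpretation code contradicted the reference range are flagged in
#'   `range_conflict` and also signalled once as a warning
#'   (class `phelab_range_conflict`); the interpretation code's call stands.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv"); make_fixture_annotations(f)
#' m <- read_annotation_tsv(f)
#' b <- fig3_bundle()
#' obs <- parse_bundle(b)$observations
#' convert_observations(obs, m)[, c("obs_id", "loinc", "hpo", "status")]
convert_observations <- function(obs, map, ont = NULL) {
  x <- resolve_outcomes(obs, map)
  ann <- as_tibble(map)[, c("loinc", "outcome_system", "outcome_code",
                            "hpo", "negated")]
  x <- left_join(x, ann, by = c("loinc", "outcome_system", "outcome_code"))

  # A-fallback for L/H without a specific entry
  fb_idx <- which(is.na(x$hpo) & is.na(x$failure) &
                    x$outcome_system == FHIR_SYSTEM &
                    x$outcome_code %in% c("L", "H"))
  if (length(fb_idx) > 0) {
    a_entries <- ann[ann$outcome_system == FHIR_SYSTEM & ann$outcome_code == "A", ]
    m <- match(x$loinc[fb_idx], a_entries$loinc)
    hit <- !is.na(m)
    x$hpo[fb_idx[hit]] <- a_entries$hpo[m[hit]]
    x$negated[fb_idx[hit]] <- a_entries$negated[m[hit]]
  }

  x$status <- case_when(
    !is.na(x$failure) ~ x$failure,
    !is.na(x$hpo) ~ "CONVERTED",
    TRUE ~ "UNMAPPED_OUTCOME"
  )
  if (!is.null(ont)) {
    missing_terms <- setdiff(unique(x$hpo[x$status == "CONVERTED"]),
                             ontology_terms(ont))
    if (length(missing_terms) > 0) {
      rlang::warn(sprintf("%d converted HPO id(s) absent from the ontology: %s",
                          length(missing_terms),
                          paste(head(missing_terms, 5), collapse = ", ")))
    }
  }
  n_conflict <- sum(x$range_conflict, na.rm = TRUE)
  if (n_conflict > 0) {
    rlang::warn(sprintf(paste("%d observation(s) carry an interpretation code that",
                              "disagrees with the reference-range inference;",
                              "the interpretation code was used"), n_conflict),
                class = "phelab_range_conflict")
  }
  x$failure <- NULL
  x
}

#' Convert a collection and tally the conversion rate
#'
#' @param obs Observations tibble.
#' @param map An [annotation_map()].
#' @param ont Optional ontology, passed through to [convert_observations()].
#' @return A list with `calls` (tibble `obs_id`, `subject_id`, `loinc`,
#'   `outcome_system`, `outcome_code`, `hpo`, `negated`, `time`), `failures`
#'   (tibble `obs_id`, `subject_id`, `loinc`, `reason`), and `rate` — the
#'   fraction of observations converted (0 for empty input). Always
#'   `nrow(calls) + nrow(failures) == nrow(obs)`.
#' @export
convert_collection <- function(obs, map, ont = NULL) {
  if (nrow(obs) == 0) {
    return(list(
      calls = tibble(obs_id = character(), subject_id = character(),
                     loinc = character(), outcome_system = character(),
                     outcome_code = character(), hpo = character(),
                     negated = logical(), time = character()),
      failures = tibble(obs_id = character(), subject_id = character(),
                        loinc = character(), reason = character()),
      rate = 0
    ))
  }
  full <- convert_observations(obs, map, ont)
  ok <- full$status == "CONVERTED"
  calls <- tibble(
    obs_id = full$obs_id[ok], subject_id = full$subject_id[ok],
    loinc = full$loinc[ok], outcome_system = full$outcome_system[ok],
    outcome_code = full$outcome_code[ok], hpo = full$hpo[ok],
    negated = full$negated[ok], time = full$effective_time[ok]
  )
  failures <- tibble(
    obs_id = full$obs_id[!ok], subject_id = full$subject_id[!ok],
    loinc = full$loinc[!ok], reason = full$status[!ok]
  )
  list(calls = calls, failures = failures, rate = nrow(calls) / nrow(obs))
}

#' Write per-observation conversion results as TSV
#'
#' @param converted Result of [convert_observations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conversion_tsv <- function(converted, path) {
  out <- converted[, c("obs_id", "subject_id", "loinc", "outcome_code",
                       "hpo", "negated", "effective_time", "status")]
  names(out)[names(out) == "effective_time"] <- "time"
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
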