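# FHIR Observation / Bundle ingestion. Targets the STU3 Observation shape
# while tolerating R4 aliases (interpretation as a single CodeableConcept or a
# list of them). Only the fields needed downstream are extracted: identity,
# LOINC code, value, reference ranges, interpretation, effective time.

loinc_systems <- c("http://loinc.org", "LOINC")

#' Parse one FHIR Observation into a normalized lab-observation row
#'
#' Extracts the LOINC coding (from `code.coding` entries whose system is
#' `http://loinc.org`, or the bare string `LOINC` for lenient fixtures), the
#' value with precedence `valueQuantity` > `valueCodeableConcept` >
#' `valueString` > missing, all reference ranges in order, and the first
#' interpretation code. Timestamps are kept as the verbatim ISO-8601 strings;
#' naive times are compared lexicographically within a patient, which is all
#' that first/last-observation reporting needs.
#'
#' @param x A file path, a JSON string, or an already-decoded list for one
#'   resource with `resourceType == "Observation"`.
#' @return A one-row tibble with columns `obs_id`, `subject_id`, `loinc`,
#'   `effective_time`, `value_type` (`"numeric"`, `"coded"`, `"text"`,
#'   `"missing"`), `value_num`, `value_unit`, `value_system`, `value_code`,
#'   `value_text`, `interpretation_raw`, and the list-column `ranges`
#'   (tibbles with `low`, `high`, `low_unit`, `high_unit`, `qualified`).
#' @export
parse_observation <- function(x) {
  res <- as_fhir_list(x)
  if (!identical(res$resourceType, "Observation")) {
    stopf("expected resourceType 'Observation', got '%s'",
          res$resourceType %||% "<none>", class = "phelab_type_error")
  }
  loinc <- extract_loinc(res$code)
  if (is.na(loinc)) {
    rlang::abort(sprintf("Observation %s carries no LOINC coding",
                         res$id %||% "<no id>"),
                 class = "phelab_no_loinc", obs_id = res$id %||% NA_character_)
  }
  subject <- res$subject$reference %||% res$subject$display %||% NA_character_
  subject <- sub("^Patient/", "", subject)
  etime <- res$effectiveDateTime %||% res$effectivePeriod$start %||%
    res$issued %||% NA_character_

  vq <- res$valueQuantity
  vc <- res$valueCodeableConcept
  vs <- res$valueString
  if (!is.null(vq)) {
    v <- list(type = "numeric", num = as.numeric(vq$value),
              unit = vq$unit %||% vq$code %||% NA_character_,
              system = NA_character_, code = NA_character_, text = NA_character_)
    if (!is.finite(v$num)) stopf("non-finite valueQuantity in Observation %s",
                                 res$id %||% "<no id>", class = "phelab_parse_error")
  } else if (!is.null(vc)) {
    coding <- if (length(vc$coding) > 0) vc$coding[[1]] else NULL
    v <- list(type = "coded", num = NA_real_, unit = NA_character_,
              system = coding$system %||% NA_character_,
              code = coding$code %||% NA_character_,
              text = vc$text %||% NA_character_)
  } else if (!is.null(vs)) {
    v <- list(type = "text", num = NA_real_, unit = NA_character_,
              system = NA_character_, code = NA_character_, text = vs)
  } else {
    v <- list(type = "missing", num = NA_real_, unit = NA_character_,
              system = NA_character_, code = NA_character_, text = NA_character_)
  }

  interp <- res$interpretation
  # R4 wraps interpretation in a list of CodeableConcepts; STU3 has one
  if (!is.null(interp) && is.null(interp$coding) && is.null(interp$text) &&
      length(interp) > 0) {
    interp <- interp[[1]]
  }
  first_coding <- if (length(interp$coding %||% list()) > 0) interp$coding[[1]] else NULL
  interp_code <- first_coding$code %||% interp$text %||% NA_character_

  rr <- res$referenceRange %||% list()
  ranges <- purrr::map_dfr(rr, function(r) {
    tibble(
      low = as.numeric(r$low$value %||% NA_real_),
      high = as.numeric(r$high$value %||% NA_real_),
      low_unit = r$low$unit %||% r$low$code %||% NA_character_,
      high_unit = r$high$unit %||% r$high$code %||% NA_character_,
      qualified = !is.null(r$age) || !is.null(r$appliesTo) ||
        (!is.null(r$type) && !identical(r$type$text %||% "normal", "normal"))
    )
  })
  if (nrow(ranges) == 0) {
    ranges <- tibble(low = double(), high = double(), low_unit = character(),
                     high_unit = character(), qualified = logical())
  }

  tibble(
    obs_id = res$id %||% NA_character_,
    subject_id = subject,
    loinc = loinc,
    effective_time = etime,
    value_type = v$type,
    value_num = v$num,
    value_unit = v$unit,
    value_system = v$system,
    value_code = v$code,
    value_text = v$text,
    interpretation_raw = interp_code,
    ranges = list(ranges)
  )
}

extract_loinc <- function(code) {
  codings <- code$coding %||% list()
  for (cd in codings) {
    if ((cd$system %||% "") %in% loinc_systems && !is.null(cd$code)) {
      return(cd$code)
    }
  }
  NA_character_
}

as_fhir_list <- function(x) {
  if (is.list(x) && !is.null(x$resourceType)) return(x)
  if (is.character(x) && length(x) == 1) {
    txt <- if (file.exists(x)) paste(readr::read_lines(x), collapse = "\n") else x
    return(tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                    error = function(e) stopf("malformed JSON: %s",
                                              conditionMessage(e),
                                              class = "phelab_parse_error")))
  }
  stopf("cannot interpret input as a FHIR resource", class = "phelab_parse_error")
}

#' Parse a FHIR Bundle of laboratory Observations
#'
#' Walks `entry[*].resource` in order. Non-Observation resources,
#' component-only panel Observations, and Observations without a LOINC coding
#' are reported as skipped (with reasons `NOT_OBSERVATION`, `COMPONENT_ONLY`,
#' `NO_LOINC`), never fatal.
#'
#' @param x A file path, JSON string, or decoded list with
#'   `resourceType == "Bundle"`.
#' @return A list with `observations` (tibble, one row per parsed Observation,
#'   input order preserved) and `skipped` (tibble `resource_id`, `reason`).
#' @export
parse_bundle <- function(x) {
  bundle <- as_fhir_list(x)
  if (!identical(bundle$resourceType, "Bundle")) {
    stopf("expected resourceType 'Bundle', got '%s'",
          bundle$resourceType %||% "<none>", class = "phelab_type_error")
  }
  entries <- bundle$entry %||% list()
  obs <- list()
  skipped <- list()
  for (e in entries) {
    res <- e$resource
    if (is.null(res) || !identical(res$resourceType, "Observation")) {
      skipped[[length(skipped) + 1L]] <-
        tibble(resource_id = res$id %||% NA_character_,
               reason = "NOT_OBSERVATION")
      next
    }
    if (!is.null(res$component) &&
        is.null(res$valueQuantity) && is.null(res$valueCodeableConcept) &&
        is.null(res$valueString) && is.null(res$interpretation)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(resource_id = res$id %||% NA_character_,
               reason = "COMPONENT_ONLY")
      next
    }
    row <- tryCatch(parse_observation(res),
                    phelab_no_loinc = function(e) e)
    if (inherits(row, "phelab_no_loinc")) {
      skipped[[length(skipped) + 1L]] <-
        tibble(resource_id = row$obs_id %||% NA_character_, reason = "NO_LOINC")
    } else {
      obs[[length(obs) + 1L]] <- row
    }
  }
  list(
    observations = if (length(obs) > 0) bind_rows(obs) else empty_observations(),
    skipped = if (length(skipped) > 0) bind_rows(skipped) else
      tibble(resource_id = character(), reason = character())
  )
}

empty_observations <- function() {
  tibble(obs_id = character(), subject_id = character(), loinc = character(),
         effective_time = character(), value_type = character(),
         value_num = double(), value_unit = character(),
         value_system = character(), value_code = character(),
         value_text = character(), interpretation_raw = character(),
         ranges = list())
}

#' Read Observations from a newline-delimited JSON stream
#'
#' One FHIR Observation per line. Skipping semantics match [parse_bundle()].
#'
#' @param path Path to an NDJSON file.
#' @return As [parse_bundle()].
#' @export
read_observations_ndjson <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- lapply(lines, function(l) {
    list(resource = jsonlite::fromJSON(l, simplifyVector = FALSE))
  })
  parse_bundle(list(resourceType = "Bundle", entry = entries))
}

#' Re-serialize a parsed observation row as a FHIR Observation list
#'
#' Inverse of [parse_observation()] for the retained fields: parsing the
#' output of `observation_to_fhir()` reproduces the input row exactly.
#'
#' @param row One row of the observations tibble.
#' @return A list representing the Observation resource (ready for
#'   `jsonlite::toJSON(auto_unbox = TRUE)`).
#' @export
observation_to_fhir <- function(row) {
  stopifnot(nrow(row) == 1)
  res <- list(
    resourceType = "Observation",
    id = row$obs_id,
    subject = list(reference = paste0("Patient/", row$subject_id)),
    code = list(coding = list(list(system = "http://loinc.org",
                                   code = row$loinc)))
  )
  if (!is.na(row$effective_time)) res$effectiveDateTime <- row$effective_time
  if (row$value_type == "numeric") {
    res$valueQuantity <- drop_null(list(value = row$value_num,
                                        unit = na_null(row$value_unit)))
  } else if (row$value_type == "coded") {
    res$valueCodeableConcept <- drop_null(list(
      coding = list(drop_null(list(system = na_null(row$value_system),
                                   code = na_null(row$value_code)))),
      text = na_null(row$value_text)))
  } else if (row$value_type == "text") {
    res$valueString <- row$value_text
  }
  if (!is.na(row$interpretation_raw)) {
    res$interpretation <- list(coding = list(list(code = row$interpretation_raw)))
  }
  rr <- row$ranges[[1]]
  if (nrow(rr) > 0) {
    res$referenceRange <- purrr::pmap(rr, function(low, high, low_unit,
                                                   high_unit, qualified) {
      r <- list()
      if (!is.na(low)) r$low <- drop_null(list(value = low, unit = na_null(low_unit)))
      if (!is.na(high)) r$high <- drop_null(list(value = high, unit = na_null(high_unit)))
      if (isTRUE(qualified)) r$appliesTo <- list(list(text = "population"))
      r
    })
  }
  res
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
na_null <- function(x) if (length(x) == 0 || is.na(x)) NULL else x
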