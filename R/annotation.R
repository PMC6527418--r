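# The LOINC -> HPO annotation map: a curated table keyed by
# (LOINC code, test outcome) whose value is an HPO term plus a negation flag.
# Quantitative (Qn) and ordinal (Ord) outcomes are keyed by internal
# interpretation codes (L/N/H/A, POS/NEG) under the system tag "FHIR";
# nominal (Nom) outcomes are keyed by an external coding such as SNOMED-CT.

# canonical TSV header -> internal column name
.ann_canonical <- c(
  loincId       = "loinc",
  loincScale    = "scale",
  outcomeSystem = "outcome_system",
  outcomeCode   = "outcome_code",
  hpoTermId     = "hpo",
  isNegated     = "negated",
  curation      = "curator",
  createdOn     = "created_on"
)

# lower-cased aliases accepted in lenient mode, covering the published
# annotation-repository layouts as far as they are known
.ann_aliases <- c(
  loincid = "loinc", loinc = "loinc", loinc_id = "loinc", loincnumber = "loinc",
  loincscale = "scale", scale = "scale", loinc_scale = "scale",
  outcomesystem = "outcome_system", system = "outcome_system",
  code_system = "outcome_system", codesystem = "outcome_system",
  outcomecode = "outcome_code", code = "outcome_code", outcome = "outcome_code",
  testresult = "outcome_code",
  hpotermid = "hpo", hpoid = "hpo", hpo_id = "hpo", hpo = "hpo",
  hpoterm = "hpo",
  isnegated = "negated", negated = "negated", is_negated = "negated",
  curation = "curator", curator = "curator", curatedby = "curator",
  createdon = "created_on", created_on = "created_on",
  datecreated = "created_on"
)

#' Construct and validate an annotation map
#'
#' Builds the keyed store mapping `(LOINC, outcome)` to an HPO term and a
#' negation flag. Input columns beyond the canonical eight are preserved
#' untouched (and re-emitted by [write_annotation_tsv()]).
#'
#' Validation enforces the structural invariants of the map:
#' * LOINC and HPO id syntax;
#' * `scale` is one of `Qn`, `Ord`, `Nom`, constant per LOINC;
#' * `(loinc, outcome_system, outcome_code)` keys are unique;
#' * `negated = TRUE` only for normal/absent outcomes (internal `N` or `NEG`) —
#'   HPO has abnormality terms only, so only a normal result may be stored as
#'   a negated abnormality;
#' * the internal code `U` (unknown) is never a valid key.
#'
#' @param x A data frame with columns `loinc`, `scale`, `outcome_system`,
#'   `outcome_code`, `hpo`, `negated`, and optionally `curator`, `created_on`.
#' @return A tibble of class `annotation_map`.
#' @seealso [read_annotation_tsv()], [annotation_lookup()], [map_statistics()]
#' @export
annotation_map <- function(x) {
  x <- as_tibble(x)
  required <- c("loinc", "scale", "outcome_system", "outcome_code", "hpo", "negated")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stopf("annotation map lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"curator" %in% names(x)) x$curator <- NA_character_
  if (!"created_on" %in% names(x)) x$created_on <- NA_character_
  x$negated <- as.logical(x$negated)
  x <- relocate(x, all_of(c(required, "curator", "created_on")))
  validate_annotation_map(x)
  class(x) <- c("annotation_map", class(tibble()))
  x
}

validate_annotation_map <- function(x, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  bad <- which(!is_loinc_id(x$loinc))
  if (length(bad) > 0) {
    stopf("malformed LOINC id %s at %s", shQuote(x$loinc[bad[1]]), where(bad[1]),
          class = "phelab_parse_error")
  }
  bad <- which(!is_hpo_id(x$hpo))
  if (length(bad) > 0) {
    stopf("malformed HPO id %s at %s", shQuote(x$hpo[bad[1]]), where(bad[1]),
          class = "phelab_parse_error")
  }
  bad <- which(!x$scale %in% loinc_scales)
  if (length(bad) > 0) {
    stopf("unknown LOINC scale %s at %s (expected Qn, Ord or Nom)",
          shQuote(x$scale[bad[1]]), where(bad[1]), class = "phelab_parse_error")
  }
  bad <- which(is.na(x$negated))
  if (length(bad) > 0) {
    stopf("isNegated must be true/false at %s", where(bad[1]),
          class = "phelab_parse_error")
  }
  internal <- x$outcome_system == FHIR_SYSTEM
  bad <- which(internal & !x$outcome_code %in% setdiff(internal_codes, "U"))
  if (length(bad) > 0) {
    stopf("invalid internal outcome code %s at %s ('U' is never an annotation key)",
          shQuote(x$outcome_code[bad[1]]), where(bad[1]),
          class = "phelab_parse_error")
  }
  bad <- which(x$negated & !(internal & x$outcome_code %in% c("N", "NEG")))
  if (length(bad) > 0) {
    stopf("negated annotation for a non-normal outcome (%s / %s) at %s",
          x$loinc[bad[1]], x$outcome_code[bad[1]], where(bad[1]),
          class = "phelab_parse_error")
  }
  key <- paste(x$loinc, x$outcome_system, x$outcome_code, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stopf("duplicate (loinc, outcome) key %s/%s at %s",
          x$loinc[dup[1]], x$outcome_code[dup[1]], where(dup[1]),
          class = "phelab_duplicate_error")
  }
  n_scale <- tapply(x$scale, x$loinc, function(s) length(unique(s)))
  if (any(n_scale > 1)) {
    offender <- names(n_scale)[n_scale > 1][1]
    stopf("LOINC %s annotated with more than one scale", offender,
          class = "phelab_consistency_error")
  }
  invisible(x)
}

#' Read an annotation map from TSV
#'
#' Reads the tab-separated annotation file. The canonical header is
#' `loincId, loincScale, outcomeSystem, outcomeCode, hpoTermId, isNegated,
#' curation, createdOn`; lines starting with `#` are ignored. In lenient mode
#' (the default) common alternative column names from published annotation
#' layouts are accepted via an alias table; `strict = TRUE` rejects anything
#' but the canonical header. Unknown extra columns are preserved.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param strict Require the canonical column names exactly.
#' @return An [annotation_map()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' make_fixture_annotations(f)
#' m <- read_annotation_tsv(f)
#' dplyr::count(m, scale)
read_annotation_tsv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  raw_lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", raw_lines) & nzchar(trimws(raw_lines))
  data_line_numbers <- which(keep)
  kept <- raw_lines[keep]
  if (length(kept) == 0) stopf("annotation file %s has no header row", path)
  df <- readr::read_tsv(I(paste0(paste(kept, collapse = "\n"), "\n")),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  lines <- data_line_numbers[-1]  # file line of each data row

  nm <- names(df)
  canon <- unname(.ann_canonical[nm])
  alias <- unname(.ann_aliases[tolower(nm)])
  mapped <- if (strict) canon else coalesce(canon, alias)
  core_targets <- c("loinc", "scale", "outcome_system", "outcome_code", "hpo", "negated")
  if (!all(core_targets %in% mapped)) {
    stopf("unrecognized annotation layout in %s (columns: %s)",
          path, paste(nm, collapse = ", "), class = "phelab_parse_error")
  }
  names(df)[!is.na(mapped)] <- mapped[!is.na(mapped)]

  neg <- tolower(trimws(df$negated))
  if (!all(neg %in% c("true", "false"))) {
    bad <- which(!neg %in% c("true", "false"))[1]
    stopf("isNegated must be 'true' or 'false' at line %s", lines[bad],
          class = "phelab_parse_error")
  }
  df$negated <- neg == "true"
  out <- tryCatch(
    {
      validate_annotation_map(as_tibble(df), lines = lines)
      annotation_map(df)
    },
    phelab_parse_error = function(e) rlang::abort(conditionMessage(e), class = class(e)[1]),
    phelab_duplicate_error = function(e) rlang::abort(conditionMessage(e), class = class(e)[1])
  )
  out
}

#' Write an annotation map to TSV
#'
#' Serializes with the canonical header, rows sorted by
#' `(loinc, outcome_system, outcome_code)` and `isNegated` as lowercase
#' `true`/`false`, so the same map always produces byte-identical output and
#' `read_annotation_tsv(write_annotation_tsv(m))` round-trips exactly. Extra
#' columns carried by the map are appended after the canonical ones.
#'
#' @param map An [annotation_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(map, path) {
  stopifnot(inherits(map, "annotation_map"))
  out <- arrange(as_tibble(map), .data$loinc, .data$outcome_system, .data$outcome_code)
  out$negated <- ifelse(out$negated, "true", "false")
  inv <- setNames(names(.ann_canonical), unname(.ann_canonical))
  names(out)[names(out) %in% names(inv)] <- inv[names(out)[names(out) %in% names(inv)]]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Look up the annotation for one (LOINC, outcome) key
#'
#' @param map An [annotation_map()].
#' @param loinc A single LOINC code.
#' @param outcome_code Outcome key: an internal interpretation code
#'   (`L`, `N`, `H`, `A`, `POS`, `NEG`) or an external code.
#' @param outcome_system `"FHIR"` for internal codes (default), else the
#'   external coding-system URI.
#' @return A one-row tibble with a `status` column: `"FOUND"` (with `hpo` and
#'   `negated` filled), `"UNMAPPED_LOINC"` (no annotation for the LOINC at
#'   all), or `"UNMAPPED_OUTCOME"` (LOINC known, this outcome not annotated).
#'   Not-found is a value, not an error.
#' @export
#' @examples
#' m <- annotation_map(tibble::tibble(
#'   loinc = "32710-6", scale = "Ord", outcome_system = "FHIR",
#'   outcome_code = c("POS", "NEG"), hpo = "HP:0031812",
#'   negated = c(FALSE, TRUE)))
#' annotation_lookup(m, "32710-6", "NEG")
annotation_lookup <- function(map, loinc, outcome_code, outcome_system = FHIR_SYSTEM) {
  stopifnot(inherits(map, "annotation_map"), length(loinc) == 1L)
  tbl <- as_tibble(map)
  hit <- tbl[tbl$loinc == loinc & tbl$outcome_system == outcome_system &
               tbl$outcome_code == outcome_code, , drop = FALSE]
  if (nrow(hit) == 1) {
    hit$status <- "FOUND"
    return(hit)
  }
  known <- any(tbl$loinc == loinc)
  tibble(loinc = loinc, scale = NA_character_, outcome_system = outcome_system,
         outcome_code = outcome_code, hpo = NA_character_, negated = NA,
         curator = NA_character_, created_on = NA_character_,
         status = if (known) "UNMAPPED_OUTCOME" else "UNMAPPED_LOINC")
}

#' Summarize an annotation map
#'
#' Computes the descriptive statistics of a mapping file: the number of
#' annotated LOINC tests by scale (with percentages), the number of distinct
#' HPO terms used, and the distribution (with mean) of how many distinct LOINC
#' tests map to each HPO term — the signal that distinct tests with equivalent
#' clinical interpretation were rolled up to one phenotype.
#'
#' @param map An [annotation_map()].
#' @return A list of class `map_statistics`: `n_entries`, `n_loinc`, `n_hpo`,
#'   `by_scale` (tibble `scale`, `n`, `pct`), `loinc_per_hpo` (tibble `hpo`,
#'   `n_loinc`), `mean_loinc_per_hpo`.
#' @export
map_statistics <- function(map) {
  stopifnot(inherits(map, "annotation_map"))
  tbl <- as_tibble(map)
  per_loinc <- distinct(tbl, .data$loinc, .data$scale)
  by_scale <- per_loinc |>
    group_by(scale = factor(.data$scale, levels = loinc_scales)) |>
    summarise(n = n(), .groups = "drop") |>
    tidyr::complete(scale, fill = list(n = 0L)) |>
    mutate(scale = as.character(scale),
           pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)
  lph <- tbl |>
    distinct(.data$hpo, .data$loinc) |>
    group_by(.data$hpo) |>
    summarise(n_loinc = n(), .groups = "drop")
  out <- list(
    n_entries = nrow(tbl),
    n_loinc = nrow(per_loinc),
    n_hpo = nrow(lph),
    by_scale = by_scale,
    loinc_per_hpo = lph,
    mean_loinc_per_hpo = if (nrow(lph) > 0) mean(lph$n_loinc) else 0
  )
  class(out) <- "map_statistics"
  out
}

#' @export
print.map_statistics <- function(x, ...) {
  cat(sprintf("Annotation map: %d entries, %d LOINC tests, %d distinct HPO terms\n",
              x$n_entries, x$n_loinc, x$n_hpo))
  for (i in seq_len(nrow(x$by_scale))) {
    cat(sprintf("  %-3s %5d (%.1f%%)\n", x$by_scale$scale[i],
                x$by_scale$n[i], x$by_scale$pct[i]))
  }
  cat(sprintf("  mean LOINC per HPO term: %.2f\n", x$mean_loinc_per_hpo))
  invisible(x)
}

#' @rdname map_statistics
#' @param x A `map_statistics` object.
#' @param ... Unused.
#' @export
tidy.map_statistics <- function(x, ...) {
  x$by_scale
}

#' @importFrom ggplot2 autoplot ggplot aes geom_col labs
#' @export
autoplot.map_statistics <- function(object, ...) {
  ggplot(object$by_scale, aes(x = .data$scale, y = .data$pct)) +
    geom_col() +
    labs(x = "LOINC scale", y = "% of annotated LOINC tests",
         title = "Annotated LOINC tests by scale")
}
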