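#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows bind_cols n n_distinct
#'   case_when coalesce row_number across all_of rename relocate pull if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_dbl map_lgl map_int map2 pmap imap keep
#' @importFrom stats glm binomial glm.control pnorm p.adjust plogis qlogis
#'   rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# id syntax ------------------------------------------------------------------

#' Validate LOINC code syntax
#'
#' A LOINC code is one to seven digits, a hyphen, and a single check digit
#' (e.g. `"6298-4"`). Only the shape is checked; mod-10 check-digit validation
#' is deliberately not applied so that synthetic codes in a reserved numeric
#' space can be used in fixtures and simulations.
#'
#' @param x Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the syntax is valid.
#' @export
#' @examples
#' is_loinc_id(c("6298-4", "HP:0002153", "6298 -4"))
is_loinc_id <- function(x) {
  !is.na(x) & grepl("^[0-9]{1,7}-[0-9]$", x)
}

#' Validate HPO term id syntax
#'
#' @param x Character vector of candidate ids (`"HP:"` plus seven digits).
#' @return Logical vector.
#' @export
#' @examples
#' is_hpo_id(c("HP:0002153", "HP:123"))
is_hpo_id <- function(x) {
  !is.na(x) & grepl("^HP:[0-9]{7}$", x)
}

loinc_scales <- c("Qn", "Ord", "Nom")
internal_codes <- c("A", "L", "N", "H", "NEG", "POS", "U")

# The coding-system tag used for internal (FHIR interpretation) outcome keys;
# anything else is an external coding system such as SNOMED-CT.
FHIR_SYSTEM <- "FHIR"

stopf <- function(fmt, ..., class = "phelab_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)
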