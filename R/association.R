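# Phenotype-association screen: for each analyzable HPO term, a logistic
# regression of the term's presence indicator on the two binary exposures
# (frequent prednisone use, acute asthma diagnosis), with odds ratios
# exp(beta), confidence intervals exp(beta -/+ ci_z * SE), and Wald p-values.

#' Decide which terms are analyzable
#'
#' A term is excluded when, among the patients classified PRESENT or ABSENT
#' for it, the majority class reaches the uniformity threshold (by default
#' 95% of the cohort sharing one value carries almost no information), or
#' when fewer than `min_patients_per_term` patients carry it.
#' INDETERMINATE patients do not enter the tally.
#'
#' @param profiles A [build_profiles()] result.
#' @param exposures Tibble `patient_id`, `frequent_prednisone`,
#'   `acute_asthma` — the patient universe of the screen.
#' @param cfg An [analysis_config()].
#' @return Tibble `term`, `n_present`, `n_absent`, `n_indeterminate`,
#'   `analyzable`, `exclusion_reason` (`UNIFORM`, `TOO_FEW_PATIENTS`, `NA`).
#' @export
filter_terms <- function(profiles, exposures, cfg = analysis_config()) {
  n_pat <- nrow(exposures)
  prof <- as_tibble(profiles) |>
    filter(!.data$negated, .data$patient_id %in% exposures$patient_id)
  tally <- prof |>
    group_by(.data$term) |>
    summarise(n_present = sum(.data$presence == "PRESENT", na.rm = TRUE),
              n_indeterminate = sum(.data$presence == "INDETERMINATE", na.rm = TRUE),
              .groups = "drop") |>
    mutate(n_absent = n_pat - .data$n_present - .data$n_indeterminate)
  tally |>
    mutate(
      majority = pmax(.data$n_present, .data$n_absent) /
        pmax(.data$n_present + .data$n_absent, 1L),
      exclusion_reason = case_when(
        .data$n_present < cfg$min_patients_per_term ~ "TOO_FEW_PATIENTS",
        .data$majority >= cfg$uniformity_threshold ~ "UNIFORM",
        TRUE ~ NA_character_
      ),
      analyzable = is.na(.data$exclusion_reason)
    ) |>
    select("term", "n_present", "n_absent", "n_indeterminate",
           "analyzable", "exclusion_reason")
}

#' Fit one logistic regression
#'
#' Maximum-likelihood logistic fit with intercept; standard errors from the
#' observed information, two-sided Wald p-values against the standard
#' normal. Degenerate inputs (constant outcome or constant exposure column)
#' and non-convergence/separation are reported as a typed status, not an
#' error.
#'
#' @param data Data frame containing the outcome and exposure columns as 0/1
#'   (or logical) values.
#' @param outcome Name of the outcome column.
#' @param exposure_cols Names of the exposure columns.
#' @return A list with `status` (`"OK"`, `"DEGENERATE"`, `"NON_CONVERGED"`)
#'   and `coefficients`: tibble `exposure`, `beta`, `se`, `p` (exposure rows
#'   only, intercept dropped).
#' @export
fit_logistic <- function(data, outcome = "outcome",
                         exposure_cols = c("frequent_prednisone", "acute_asthma")) {
  y <- as.numeric(data[[outcome]])
  empty <- tibble(exposure = exposure_cols, beta = NA_real_, se = NA_real_,
                  p = NA_real_)
  if (length(unique(y)) < 2 ||
      any(vapply(exposure_cols,
                 function(v) length(unique(as.numeric(data[[v]]))) < 2,
                 logical(1)))) {
    return(list(status = "DEGENERATE", coefficients = empty))
  }
  fml <- stats::reformulate(exposure_cols, response = outcome)
  df <- data
  df[[outcome]] <- y
  fit <- suppressWarnings(
    glm(fml, family = binomial(), data = df,
        control = glm.control(epsilon = 1e-10, maxit = 100))
  )
  cf <- summary(fit)$coefficients
  rows <- match(exposure_cols, rownames(cf))
  # logical exposures appear as e.g. "frequent_prednisoneTRUE"
  if (anyNA(rows)) rows <- match(paste0(exposure_cols, "TRUE"), rownames(cf))
  beta <- cf[rows, "Estimate"]
  se <- cf[rows, "Std. Error"]
  status <- if (!fit$converged || any(abs(beta) > 15) || any(se > 15)) {
    "NON_CONVERGED"
  } else {
    "OK"
  }
  list(status = status,
       coefficients = tibble(exposure = exposure_cols, beta = unname(beta),
                             se = unname(se),
                             p = unname(2 * pnorm(-abs(beta / se)))))
}

#' Screen every analyzable phenotype for exposure association
#'
#' For each term passing [filter_terms()], builds the per-patient design:
#' outcome 1 for PRESENT, 0 for ABSENT, INDETERMINATE patients dropped
#' (patients never assigned the term are ABSENT), fits the logistic model on
#' both exposures jointly, and derives odds ratios `exp(beta)`, confidence
#' intervals `exp(beta -/+ ci_z * SE)`, Wald p-values, and significance
#' markers (`**` p<0.01, `*` p<0.05, `-` otherwise). A Benjamini-Hochberg
#' adjusted p-value column is reported alongside for transparency but does
#' not drive the markers. Deterministic given its inputs.
#'
#' @param profiles A [build_profiles()] result.
#' @param exposures Tibble `patient_id`, `frequent_prednisone`, `acute_asthma`.
#' @param ont Optional ontology for term labels.
#' @param cfg An [analysis_config()].
#' @return A tibble of class `phenotype_screen`: one row per term and
#'   exposure with `term`, `label`, `n_used`, `exposure`, `beta`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `p_bh`, `significance`,
#'   `status`. Terms excluded up front are recorded in
#'   `attr(, "excluded_terms")`.
#' @export
run_screen <- function(profiles, exposures, ont = NULL, cfg = analysis_config()) {
  ft <- filter_terms(profiles, exposures, cfg)
  prof <- as_tibble(profiles) |> filter(!.data$negated)
  analyzable <- ft$term[ft$analyzable]

  rows <- purrr::map(analyzable, function(tm) {
    pres <- prof[prof$term == tm, c("patient_id", "presence")]
    d <- exposures |>
      left_join(pres, by = "patient_id") |>
      mutate(presence = coalesce(.data$presence, "ABSENT")) |>
      filter(.data$presence != "INDETERMINATE") |>
      mutate(outcome = as.integer(.data$presence == "PRESENT"))
    fit <- fit_logistic(d, "outcome", c("frequent_prednisone", "acute_asthma"))
    fit$coefficients |>
      mutate(term = tm, n_used = nrow(d), status = fit$status,
             .before = 1)
  })
  out <- if (length(rows) > 0) bind_rows(rows) else
    tibble(term = character(), n_used = integer(), status = character(),
           exposure = character(), beta = double(), se = double(), p = double())
  out <- out |>
    mutate(
      odds_ratio = exp(.data$beta),
      ci_low = exp(.data$beta - cfg$ci_z * .data$se),
      ci_high = exp(.data$beta + cfg$ci_z * .data$se),
      significance = case_when(
        is.na(.data$p) ~ NA_character_,
        .data$p < 0.01 ~ "**",
        .data$p < 0.05 ~ "*",
        TRUE ~ "-"
      )
    ) |>
    group_by(.data$exposure) |>
    mutate(p_bh = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    select("term", "n_used", "exposure", "beta", "se", "odds_ratio",
           "ci_low", "ci_high", "p", "p_bh", "significance", "status") |>
    arrange(.data$term, .data$exposure)
  if (!is.null(ont)) {
    out <- mutate(out, label = term_label(ont, .data$term), .after = "term")
  }
  class(out) <- c("phenotype_screen", class(tibble()))
  attr(out, "excluded_terms") <- filter(ft, !ft$analyzable)
  attr(out, "config") <- cfg
  out
}

#' Format a screen as an odds-ratio report table
#'
#' One row per term, sorted descending by the chosen exposure's odds ratio,
#' with `OR [low-high] p` style columns per exposure and the significance
#' markers. Optionally keeps only terms whose odds ratio for the sort
#' exposure exceeds 1.
#'
#' @param screen A [run_screen()] result.
#' @param sort_by Exposure name to sort by (default `"acute_asthma"`).
#' @param or_greater_than_1 Keep only rows with `odds_ratio > 1` for the
#'   sort exposure.
#' @return A wide tibble, one row per term.
#' @export
odds_ratio_table <- function(screen, sort_by = "acute_asthma",
                             or_greater_than_1 = FALSE) {
  x <- as_tibble(screen)
  if (nrow(x) == 0) return(tibble(term = character()))
  fmt <- x |>
    mutate(formatted = sprintf("%.2f [%.2f-%.2f] %.3g %s", .data$odds_ratio,
                               .data$ci_low, .data$ci_high, .data$p,
                               .data$significance))
  keep_cols <- intersect(c("term", "label", "n_used"), names(fmt))
  wide <- fmt |>
    select(all_of(keep_cols), "exposure", "odds_ratio", "formatted") |>
    tidyr::pivot_wider(names_from = "exposure",
                       values_from = c("odds_ratio", "formatted"))
  ord_col <- paste0("odds_ratio_", sort_by)
  if (!ord_col %in% names(wide)) {
    stopf("exposure %s not present in screen", sort_by)
  }
  if (or_greater_than_1) wide <- filter(wide, .data[[ord_col]] > 1)
  arrange(wide, dplyr::desc(.data[[ord_col]]))
}

#' @rdname run_screen
#' @param x A `phenotype_screen`.
#' @param ... Unused.
#' @export
tidy.phenotype_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname run_screen
#' @export
glance.phenotype_screen <- function(x, ...) {
  tibble(
    n_terms = n_distinct(x$term),
    n_excluded = nrow(attr(x, "excluded_terms") %||% tibble()),
    n_non_converged = n_distinct(x$term[x$status != "OK"]),
    n_sig_05 = sum(x$p < 0.05, na.rm = TRUE),
    n_sig_01 = sum(x$p < 0.01, na.rm = TRUE)
  )
}

#' Forest plot of a phenotype screen
#'
#' Odds ratios with confidence intervals per term, faceted by exposure, on a
#' log scale.
#'
#' @param object A [run_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 geom_point geom_errorbarh geom_vline facet_wrap
#'   scale_x_log10 aes
#' @export
autoplot.phenotype_screen <- function(object, ...) {
  x <- as_tibble(object)
  x$display <- if ("label" %in% names(x)) coalesce(x$label, x$term) else x$term
  ggplot(x, aes(x = .data$odds_ratio,
                y = stats::reorder(.data$display, .data$odds_ratio))) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    facet_wrap(~exposure) +
    labs(x = "odds ratio (log scale)", y = NULL,
         title = "Phenotype association screen")
}

#' Write a screen report as TSV
#'
#' @param screen A [run_screen()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  readr::write_tsv(as_tibble(screen), path, na = "", progress = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
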