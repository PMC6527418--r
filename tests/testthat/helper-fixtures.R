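# Shared in-code fixtures: observation rows, random annotation maps, random
# DAGs with an independent reachability oracle.

make_obs <- function(obs_id = "o1", subject = "p1", loinc = "6298-4",
                     value = NA_real_, unit = NA_character_,
                     low = NA_real_, high = NA_real_, runit = unit,
                     interp = NA_character_, time = NA_character_,
                     value_code = NA_character_, value_system = NA_character_,
                     value_text = NA_character_) {
  value_type <- if (!is.na(value)) "numeric"
  else if (!is.na(value_code)) "coded"
  else if (!is.na(value_text)) "text"
  else "missing"
  ranges <- if (!is.na(low) || !is.na(high)) {
    tibble::tibble(low = low, high = high, low_unit = runit, high_unit = runit,
                   qualified = FALSE)
  } else {
    tibble::tibble(low = double(), high = double(), low_unit = character(),
                   high_unit = character(), qualified = logical())
  }
  tibble::tibble(
    obs_id = obs_id, subject_id = subject, loinc = loinc,
    effective_time = time, value_type = value_type, value_num = value,
    value_unit = unit, value_system = value_system, value_code = value_code,
    value_text = value_text, interpretation_raw = interp,
    ranges = list(ranges)
  )
}

# random valid annotation map with n LOINC tests
random_annotation_map <- function(n, seed) {
  set.seed(seed)
  loincs <- sprintf("%d-%d", sample(10000:99999, n), sample(0:9, n, replace = TRUE))
  scales <- sample(c("Qn", "Ord", "Nom"), n, replace = TRUE, prob = c(.6, .3, .1))
  rows <- lapply(seq_len(n), function(i) {
    hpo <- sprintf("HP:%07d", sample(1:99999, 1))
    if (scales[i] == "Qn") {
      codes <- sample(c("L", "H", "A"), sample(1:3, 1))
      out <- tibble::tibble(loinc = loincs[i], scale = "Qn",
                            outcome_system = "FHIR", outcome_code = codes,
                            hpo = hpo, negated = FALSE)
      if (runif(1) < 0.5) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          loinc = loincs[i], scale = "Qn", outcome_system = "FHIR",
          outcome_code = "N", hpo = hpo, negated = TRUE))
      }
      out
    } else if (scales[i] == "Ord") {
      tibble::tibble(loinc = loincs[i], scale = "Ord", outcome_system = "FHIR",
                     outcome_code = c("POS", "NEG"), hpo = hpo,
                     negated = c(FALSE, TRUE))
    } else {
      k <- sample(1:3, 1)
      tibble::tibble(loinc = loincs[i], scale = "Nom",
                     outcome_system = "http://snomed.info/sct",
                     outcome_code = sprintf("%09d", sample(1:999999, k)),
                     hpo = sprintf("HP:%07d", sample(1:99999, k)),
                     negated = FALSE)
    }
  })
  annotation_map(dplyr::bind_rows(rows))
}

# random DAG on n nodes: edges only from higher to lower index, so acyclic
random_dag <- function(n, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("HP:%07d", seq_len(n))
  edges <- list()
  for (i in 2:n) {
    parents <- which(runif(i - 1) < p_edge)
    if (length(parents) == 0) parents <- sample(seq_len(i - 1), 1)
    edges[[i]] <- tibble::tibble(child = ids[i], parent = ids[parents])
  }
  list(ids = ids,
       terms = tibble::tibble(id = ids, label = ids),
       edges = dplyr::bind_rows(edges))
}

# independent reachability oracle: boolean matrix closure over child->parent
# adjacency, nothing shared with the package's BFS
reach_oracle <- function(ids, edges) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  A[cbind(match(edges$child, ids), match(edges$parent, ids))] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

fixture_cfg <- function(...) {
  analysis_config(min_patients_per_term = 1L, ...)
}
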