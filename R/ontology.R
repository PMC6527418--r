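# Ontology loading and ancestor propagation. Terms form a rooted DAG via
# is_a edges; a patient assigned an abnormality term is inferred to carry
# every ancestor abnormality as well, stopping below the uninformative roots
# ("Phenotypic abnormality" and "All").

#' Default propagation stop set
#'
#' Terms that would otherwise be assigned to every patient: the ontology root
#' (`HP:0000001`, "All") and `HP:0000118` ("Phenotypic abnormality").
#' Everything strictly below `HP:0000118` is eligible for propagation.
#' @export
DEFAULT_STOP_SET <- c("HP:0000118", "HP:0000001")

#' Construct an ontology from a term table and is_a edges
#'
#' @param terms Tibble with columns `id`, `label`, and optionally `obsolete`
#'   (logical) and `replaced_by`.
#' @param edges Tibble with columns `child`, `parent` (is_a edges).
#' @param alt_ids Optional named character vector mapping alternate ids to
#'   primary ids.
#' @return An object of class `hpo_ontology`.
#' @export
ontology <- function(terms, edges, alt_ids = character()) {
  terms <- as_tibble(terms)
  if (!"obsolete" %in% names(terms)) terms$obsolete <- FALSE
  if (!"replaced_by" %in% names(terms)) terms$replaced_by <- NA_character_
  terms$obsolete <- terms$obsolete %na% FALSE
  edges <- as_tibble(edges)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown) > 0) {
    stopf("is_a edge references unknown term(s): %s",
          paste(head(unknown, 5), collapse = ", "),
          class = "phelab_structural_error")
  }
  assert_acyclic(terms$id, edges)
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  structure(
    list(terms = terms, edges = edges, parents = parents, alt_ids = alt_ids),
    class = "hpo_ontology"
  )
}

assert_acyclic <- function(ids, edges) {
  # Kahn's algorithm on the child -> parent graph
  indeg <- table(factor(edges$parent, levels = ids))
  active <- setNames(as.integer(indeg), ids)
  queue <- ids[active == 0]
  seen <- 0L
  by_child <- split(edges$parent, factor(edges$child, levels = ids))
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    # removing v decrements the in-degree of nothing in child->parent order;
    # treat edges as child -> parent and peel terms whose children are done
    for (p in by_child[[v]]) {
      active[p] <- active[p] - 1L
      if (active[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(ids)) {
    stopf("cycle detected in is_a graph", class = "phelab_structural_error")
  }
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms (%d obsolete), %d is_a edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Term ids of an ontology
#' @param ont An `hpo_ontology`.
#' @param include_obsolete Keep obsolete term ids.
#' @return Character vector of term ids.
#' @export
ontology_terms <- function(ont, include_obsolete = TRUE) {
  ids <- ont$terms$id
  if (!include_obsolete) ids <- ids[!ont$terms$obsolete]
  ids
}

#' Label of ontology terms
#' @param ont An `hpo_ontology`.
#' @param ids Term ids.
#' @return Character vector of labels (`NA` for unknown ids).
#' @export
term_label <- function(ont, ids) {
  ont$terms$label[match(ids, ont$terms$id)]
}

resolve_term <- function(ont, id) {
  if (id %in% ont$terms$id) return(id)
  if (id %in% names(ont$alt_ids)) return(unname(ont$alt_ids[[id]]))
  NA_character_
}

#' Load an ontology from OBO or obographs JSON
#'
#' Supports OBO 1.2 flat files (`[Term]` stanzas with `id`, `name`, `is_a`,
#' `alt_id`, `is_obsolete`, `replaced_by`) and obographs-style ontology JSON
#' (`graphs[].nodes` / `graphs[].edges` with `is_a`/`subClassOf`
#' predicates). Obsolete terms are retained in the term table but excluded
#' from all closures; alternate ids resolve to their primary id.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"obo"`, or `"json"`.
#' @return An [ontology()] object.
#' @export
load_ontology <- function(path, format = c("auto", "obo", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "obo"
  }
  if (!file.exists(path)) stopf("ontology file not found: %s", path)
  switch(format, obo = parse_obo(path), json = parse_obograph(path))
}

parse_obo <- function(path) {
  lines <- readr::read_lines(path)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) {
    stopf("no [Term] stanzas found in %s", path, class = "phelab_parse_error")
  }
  bounds <- c(stanza_starts, length(lines) + 1L)
  terms <- vector("list", length(stanza_starts))
  edges <- list()
  alt <- character()
  for (i in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    fields <- sub(":.*$", "", chunk)
    values <- trimws(sub("^[a-z_]+:", "", chunk))
    id <- values[fields == "id"][1]
    name <- values[fields == "name"]
    isa <- trimws(sub("!.*$", "", values[fields == "is_a"]))
    alt_ids <- values[fields == "alt_id"]
    obsolete <- any(fields == "is_obsolete" & tolower(values) == "true")
    repl <- values[fields == "replaced_by"]
    terms[[i]] <- tibble(id = id,
                         label = if (length(name) > 0) name[1] else NA_character_,
                         obsolete = obsolete,
                         replaced_by = if (length(repl) > 0) repl[1] else NA_character_)
    if (length(isa) > 0) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = isa)
    }
    if (length(alt_ids) > 0) {
      alt[alt_ids] <- id
    }
  }
  terms <- bind_rows(terms)
  edges <- if (length(edges) > 0) bind_rows(edges) else
    tibble(child = character(), parent = character())
  ontology(terms, edges, alt_ids = alt)
}

parse_obograph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  graph <- doc$graphs[[1]]
  curie <- function(x) sub("^.*[/#]([A-Za-z]+)_([0-9]+)$", "\\1:\\2", x)
  nodes <- purrr::map_dfr(graph$nodes, function(n) {
    tibble(id = curie(n$id),
           label = n$lbl %||% NA_character_,
           obsolete = isTRUE(n$meta$deprecated),
           replaced_by = NA_character_)
  })
  edges <- purrr::map_dfr(graph$edges, function(e) {
    pred <- e$pred %||% ""
    if (pred %in% c("is_a", "subClassOf") || grepl("subClassOf$", pred)) {
      tibble(child = curie(e$sub), parent = curie(e$obj))
    } else {
      tibble(child = character(), parent = character())
    }
  })
  ontology(nodes, edges)
}

#' Ancestor closure of a term
#'
#' Transitive is_a closure of `term`, excluding the term itself, traversed
#' upward without entering obsolete terms or members of `stop_set` (so
#' anything lying above the term only via stop-set members is excluded
#' too). With the default stop set, propagation never reaches "Phenotypic
#' abnormality" or the root.
#'
#' @param ont An [ontology()] object.
#' @param term A single term id (alternate ids are resolved).
#' @param stop_set Character vector of term ids not to enter.
#' @return Character vector of ancestor ids (possibly empty).
#' @export
ancestors <- function(ont, term, stop_set = DEFAULT_STOP_SET) {
  t0 <- resolve_term(ont, term)
  if (is.na(t0)) {
    stopf("term %s not found in ontology", term, class = "phelab_not_found")
  }
  obsolete_ids <- ont$terms$id[ont$terms$obsolete]
  blocked <- c(stop_set, obsolete_ids)
  seen <- character()
  frontier <- t0
  while (length(frontier) > 0) {
    nxt <- unique(unlist(ont$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, blocked, t0))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Propagate observation counts up the ontology
#'
#' Augments a per-term observation-count profile with ancestor terms: each
#' source observation contributes at most once to each ancestor (union
#' semantics over distinct asserted terms — a diamond in the DAG does not
#' double-count), asserted counts are unchanged, and the result is idempotent
#' (re-propagating an already-propagated profile changes nothing, because
#' only asserted rows propagate).
#'
#' Only non-negated abnormality counts should be supplied: negation does not
#' propagate in either direction.
#'
#' @param profile Tibble with columns `term`, `count` (non-negative), and
#'   optionally `asserted` (logical; defaults to all `TRUE` on first
#'   propagation).
#' @param ont An [ontology()] object.
#' @param stop_set Passed to [ancestors()].
#' @return Tibble `term`, `asserted`, `asserted_count`, `count` where `count`
#'   is the propagated count (pointwise >= the input). Terms absent from the
#'   ontology are kept unpropagated and listed in `attr(, "skipped")`.
#' @export
propagate_counts <- function(profile, ont, stop_set = DEFAULT_STOP_SET) {
  profile <- as_tibble(profile)
  if (!"asserted" %in% names(profile)) profile$asserted <- TRUE
  if (any(profile$count < 0)) stopf("counts must be non-negative")
  # on re-propagation, only the originally asserted counts feed the closure
  cnt_col <- if ("asserted_count" %in% names(profile)) "asserted_count" else "count"
  ass <- tibble(term = profile$term[profile$asserted],
                count = profile[[cnt_col]][profile$asserted])
  known <- vapply(ass$term, function(t) !is.na(resolve_term(ont, t)), logical(1))
  skipped <- ass$term[!known]

  anc_map <- purrr::map(ass$term[known], function(t) c(t, ancestors(ont, t, stop_set)))
  contrib <- tibble(
    term = c(unlist(anc_map, use.names = FALSE), skipped),
    n = rep(c(ass$count[known], ass$count[!known]),
            times = c(lengths(anc_map), rep(1L, length(skipped))))
  )
  out <- contrib |>
    group_by(.data$term) |>
    summarise(count = sum(.data$n), .groups = "drop") |>
    left_join(ass |> rename(asserted_count = "count"), by = "term") |>
    mutate(asserted_count = coalesce(.data$asserted_count, 0),
           asserted = .data$asserted_count > 0) |>
    select("term", "asserted", "asserted_count", "count") |>
    arrange(.data$term)
  attr(out, "skipped") <- skipped
  out
}
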