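#' Parse an OBO-format ontology
#'
#' Reads an OBO 1.2/1.4 flat file into an ontology graph. Only `[Term]`
#' stanzas are interpreted; `is_a` and `relationship: part_of` lines become
#' closure edges (the GO annotation-propagation convention), all other
#' relationship types are ignored. Obsolescence metadata (`is_obsolete`,
#' `replaced_by`) is captured so that annotations to retired terms can be
#' rewritten or dropped downstream.
#'
#' @param x Path to an OBO file, or the document itself as a character
#'   string/vector of lines.
#' @return An object of class `ontology_graph`: a list with
#'   * `terms`: tibble with columns `id`, `name`, `namespace`, `obsolete`,
#'     `replaced_by`;
#'   * `edges`: tibble with columns `child`, `parent`, `relation`
#'     (`is_a` or `part_of`).
#'   Closure edges out of obsolete terms are dropped (the true-path closure
#'   never traverses a retired term).
#' @details Trailing `! ...` comments on `is_a`/`relationship` lines are
#'   tolerated, as emitted by standard GO releases. A cyclic `is_a` structure
#'   is an error (the cycle is listed); a stanza without an `id` is an error
#'   naming the stanza ordinal.
#' @seealso [go_ancestors()], [go_descendants()], [resolve_term()],
#'   [write_obo()]
#' @export
parse_obo <- function(x) {
  lines <- input_lines(x)
  lines <- sub("\r$", "", lines)

  # split into stanzas
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) {
    abort("no [Term] stanza found in OBO input", class = "phyloanno_parse_error")
  }
  bounds <- c(stanza_starts, length(lines) + 1L)

  terms <- list()
  edges <- list()
  ordinal <- 0L
  for (i in seq_along(stanza_starts)) {
    head_line <- lines[stanza_starts[i]]
    if (!identical(trimws(head_line), "[Term]")) next
    ordinal <- ordinal + 1L
    body <- lines[seq(stanza_starts[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", character(1))
    vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else "", character(1))
    # strip trailing "! ..." comments
    vals <- trimws(sub("\\s*!.*$", "", vals))

    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      abort(sprintf("OBO [Term] stanza %d is missing an id", ordinal),
            class = "phyloanno_parse_error")
    }
    obsolete <- any(keys == "is_obsolete" & vals == "true")
    replaced <- vals[keys == "replaced_by"]
    replaced <- if (length(replaced)) replaced[1] else NA_character_
    nm <- vals[keys == "name"]
    ns <- vals[keys == "namespace"]
    terms[[length(terms) + 1L]] <- tibble(
      id = id,
      name = if (length(nm)) nm[1] else NA_character_,
      namespace = if (length(ns)) ns[1] else NA_character_,
      obsolete = obsolete,
      replaced_by = replaced
    )
    isa_parents <- vals[keys == "is_a"]
    for (p in isa_parents) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = p, relation = "is_a")
    }
    rels <- vals[keys == "relationship"]
    for (r in rels) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        edges[[length(edges) + 1L]] <- tibble(child = id, parent = parts[2],
                                              relation = "part_of")
      }
    }
  }
  if (length(terms) == 0) {
    abort("no [Term] stanza found in OBO input", class = "phyloanno_parse_error")
  }
  terms <- bind_rows(terms)
  if (anyDuplicated(terms$id)) {
    abort(sprintf("duplicate term id(s): %s",
                  paste(unique(terms$id[duplicated(terms$id)]), collapse = ", ")),
          class = "phyloanno_parse_error")
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(child = character(), parent = character(), relation = character())

  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing)) {
    abort(sprintf("edge references unknown term(s): %s",
                  paste(missing, collapse = ", ")),
          class = "phyloanno_parse_error")
  }
  # obsolete terms take no part in the closure
  obs <- terms$id[terms$obsolete]
  edges <- edges[!(edges$child %in% obs), , drop = FALSE]

  g <- new_ontology_graph(terms, edges)
  cyc <- find_cycle(g)
  if (!is.null(cyc)) {
    abort(sprintf("cyclic ontology structure: %s", paste(cyc, collapse = " -> ")),
          class = "phyloanno_cycle_error")
  }
  g
}

new_ontology_graph <- function(terms, edges) {
  structure(
    list(
      terms = as_tibble(terms),
      edges = as_tibble(edges),
      parents_of = split(edges$parent, factor(edges$child, levels = terms$id)),
      children_of = split(edges$child, factor(edges$parent, levels = terms$id))
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms, %d edges (%d obsolete)\n",
              nrow(x$terms), nrow(x$edges), sum(x$terms$obsolete)))
  invisible(x)
}

# Kahn's algorithm; returns NULL if acyclic, else one cycle as a vector of ids.
find_cycle <- function(graph) {
  ids <- graph$terms$id
  indeg <- vapply(graph$children_of[ids], length, integer(1))
  queue <- ids[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in graph$parents_of[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parent links inside the residual subgraph until a repeat
  residual <- names(indeg)[indeg > 0]
  v <- residual[1]; path <- character()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(graph$parents_of[[v]], residual)[1]
  }
  c(path[which(path == v):length(path)], v)
}

check_term <- function(graph, term) {
  if (!(term %in% graph$terms$id)) {
    abort(sprintf("unknown term: %s", term), class = "phyloanno_lookup_error")
  }
}

#' Ancestors of a term under the true-path rule
#'
#' Transitive closure of `is_a` and `part_of` edges above a term. An
#' annotation to a term implies annotation to every term returned here
#' (the true-path rule).
#'
#' @param graph An `ontology_graph`.
#' @param term A GO identifier.
#' @param reflexive Include `term` itself?
#' @return Character vector of term ids.
#' @export
go_ancestors <- function(graph, term, reflexive = FALSE) {
  check_term(graph, term)
  if (graph$terms$obsolete[match(term, graph$terms$id)]) {
    abort(sprintf("term %s is obsolete", term),
          class = "phyloanno_obsolete_term",
          replaced_by = graph$terms$replaced_by[match(term, graph$terms$id)])
  }
  closure_walk(graph$parents_of, term, reflexive)
}

#' Descendants of a term
#'
#' Transitive closure of `is_a`/`part_of` edges below a term: the set of
#' more specific terms whose annotation implies `term`.
#'
#' @inheritParams go_ancestors
#' @return Character vector of term ids.
#' @export
go_descendants <- function(graph, term, reflexive = FALSE) {
  check_term(graph, term)
  closure_walk(graph$children_of, term, reflexive)
}

closure_walk <- function(adj, start, reflexive) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (reflexive) unique(c(start, seen)) else seen
}

#' Resolve a possibly-obsolete term to a current one
#'
#' Current terms map to themselves; obsolete terms follow their
#' `replaced_by` pointer. Obsolete terms without a replacement cannot be
#' resolved automatically — the caller must drop the annotation or
#' re-curate — and raise an `phyloanno_unresolvable_term` condition.
#' (`consider:` suggestions are deliberately not followed: they are
#' ambiguous and demand curator choice.)
#'
#' @inheritParams go_ancestors
#' @return A current GO identifier.
#' @export
resolve_term <- function(graph, term) {
  check_term(graph, term)
  row <- match(term, graph$terms$id)
  if (!graph$terms$obsolete[row]) return(term)
  rep <- graph$terms$replaced_by[row]
  if (is.na(rep) || !nzchar(rep)) {
    abort(sprintf("term %s is obsolete with no replacement", term),
          class = "phyloanno_unresolvable_term")
  }
  rep
}

#' Serialize an ontology graph to OBO format
#'
#' Deterministic writer (terms sorted by id, edge lines sorted) so that
#' `parse_obo(write_obo(g))` reproduces `g` exactly.
#'
#' @param graph An `ontology_graph`.
#' @param file Optional path; when given the document is written there.
#' @return The OBO document as a single string, invisibly when `file` is set.
#' @export
write_obo <- function(graph, file = NULL) {
  out <- c("format-version: 1.2", "")
  terms <- graph$terms[order(graph$terms$id), , drop = FALSE]
  for (i in seq_len(nrow(terms))) {
    t <- terms[i, ]
    stanza <- c("[Term]", paste0("id: ", t$id))
    if (!is.na(t$name)) stanza <- c(stanza, paste0("name: ", t$name))
    if (!is.na(t$namespace)) stanza <- c(stanza, paste0("namespace: ", t$namespace))
    e <- graph$edges[graph$edges$child == t$id, , drop = FALSE]
    e <- e[order(e$relation, e$parent), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      stanza <- c(stanza, if (e$relation[j] == "is_a") {
        paste0("is_a: ", e$parent[j])
      } else {
        paste0("relationship: part_of ", e$parent[j])
      })
    }
    if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
    if (!is.na(t$replaced_by)) stanza <- c(stanza, paste0("replaced_by: ", t$replaced_by))
    out <- c(out, stanza, "")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    write_lines_file(out, file)
    return(invisible(txt))
  }
  txt
}

#' Lint an ontology graph
#'
#' Reports structural oddities that are legal but worth curator attention:
#' currently `part_of` edges that cross namespaces (e.g. a cellular
#' component part of a biological process). Aspect/namespace agreement of
#' annotations is enforced at the GAF layer, not here.
#'
#' @param graph An `ontology_graph`.
#' @return Tibble with columns `child`, `parent`, `relation`, `note`.
#' @export
ontology_lint <- function(graph) {
  ns <- graph$terms$namespace[match(graph$edges$child, graph$terms$id)]
  np <- graph$terms$namespace[match(graph$edges$parent, graph$terms$id)]
  cross <- graph$edges$relation == "part_of" & !is.na(ns) & !is.na(np) & ns != np
  out <- graph$edges[cross, , drop = FALSE]
  out$note <- if (nrow(out)) "cross-namespace part_of" else character(0)
  as_tibble(out)
}
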