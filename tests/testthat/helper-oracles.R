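# Independent brute-force oracles. These deliberately use different
# algorithms (and igraph where possible) than the package internals.

oracle_term_closure <- function(graph, term, mode) {
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("child", "parent")], directed = TRUE,
    vertices = graph$terms$id)
  setdiff(names(igraph::subcomponent(ig, term, mode = mode)), term)
}

oracle_ancestors <- function(graph, term) oracle_term_closure(graph, term, "out")

oracle_descendants <- function(graph, term) oracle_term_closure(graph, term, "in")

# MRCA by counting how many inputs each node dominates, then taking the
# deepest node dominating all of them
oracle_mrca <- function(tree, ids) {
  ids <- unique(vapply(ids, function(i) phyloanno:::resolve_node(tree, i),
                       character(1)))
  tab <- table(unlist(lapply(ids, function(i) {
    phyloanno:::path_to_root(tree, i)
  })))
  common <- names(tab)[tab == length(ids)]
  depth <- phyloanno:::node_depths(tree)
  common[which.max(depth[common])]
}

# IBA target set by per-node path walking: a node receives IBA from gain g
# iff g lies on its root path and no blocking loss node lies on the path
# segment from the node up to (but excluding) g
oracle_iba_targets <- function(tree, gain_node, blocking_loss_nodes) {
  all_nodes <- tree$nodes$node_id
  keep <- vapply(all_nodes, function(v) {
    if (v == gain_node) return(FALSE)
    path <- phyloanno:::path_to_root(tree, v)
    gpos <- match(gain_node, path)
    if (is.na(gpos)) return(FALSE)
    segment <- path[seq_len(gpos - 1)]  # v .. just below g
    !any(segment %in% blocking_loss_nodes)
  }, logical(1))
  unname(all_nodes[keep])
}

# which losses of a model block a gain term, using the igraph ancestor oracle
oracle_blocking_losses <- function(tree, ontology, model, gain_node, gain_term) {
  l <- model$losses
  if (nrow(l) == 0) return(character())
  below <- oracle_iba_targets(tree, gain_node, character())
  anc <- c(gain_term, oracle_ancestors(ontology, gain_term))
  l$node_id[l$node_id %in% below & l$go_id %in% anc]
}

# minimum loss-set cardinality by exhaustive search over subsets of
# increasing size: a subset is valid when it covers every N leaf below the
# gain and covers no P leaf
oracle_min_losses <- function(tree, gain_node, P, N) {
  candidates <- tree_descendants(tree, gain_node)
  leaves_below <- tree_descendants(tree, gain_node, leaves_only = TRUE)
  N_g <- intersect(N, leaves_below)
  if (length(N_g) == 0) return(0L)
  covered <- lapply(candidates, function(v) {
    phyloanno:::leaves_under(tree, v)
  })
  names(covered) <- candidates
  for (k in seq(1L, length(candidates))) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    for (S in combos) {
      cov <- unique(unlist(covered[S], use.names = FALSE))
      if (all(N_g %in% cov) && !any(P %in% cov)) return(k)
    }
  }
  stop("no valid loss set found")  # cannot happen: leaves of N_g are valid
}

# independent recount of family statistics by plain loops
oracle_family_stats <- function(tree, usable_records, inferred) {
  leaves <- tree$nodes$node_id[tree$nodes$is_leaf]
  rec <- usable_records[usable_records$object_id %in% leaves, , drop = FALSE]
  iba_leaf_targets <- character()
  ibd <- 0L; iba <- 0L; ibd_terms <- character()
  for (i in seq_len(nrow(inferred))) {
    ev <- inferred$evidence[i]
    if (ev == "IBD") {
      ibd <- ibd + 1L
      ibd_terms <- c(ibd_terms, inferred$go_id[i])
    } else if (ev == "IBA") {
      iba <- iba + 1L
      if (inferred$target[i] %in% leaves) {
        iba_leaf_targets <- c(iba_leaf_targets, inferred$target[i])
      }
    }
  }
  list(protein_count = length(leaves),
       exp_proteins = length(unique(rec$object_id)),
       exp_annotations = nrow(rec),
       exp_terms = length(unique(rec$go_id)),
       annotated_proteins = length(unique(iba_leaf_targets)),
       ibd_count = ibd, iba_count = iba,
       inferred_terms = length(unique(ibd_terms)))
}

# independent new-annotation scan: record x closure brute force
oracle_new_annotations <- function(inferred, usable_records, ontology) {
  out <- character()
  for (i in seq_len(nrow(inferred))) {
    if (inferred$evidence[i] != "IBA" || !inferred$is_leaf[i]) next
    gene <- inferred$target[i]
    term <- inferred$go_id[i]
    ok_terms <- c(term, oracle_descendants(ontology, term))
    supported <- FALSE
    for (j in seq_len(nrow(usable_records))) {
      if (usable_records$object_id[j] == gene &&
          usable_records$go_id[j] %in% ok_terms) {
        supported <- TRUE
        break
      }
    }
    if (!supported) out <- c(out, paste(gene, term, sep = "\r"))
  }
  sort(unique(out))
}

# brute-force presence/negation scan over records x closure
oracle_presence_sets <- function(tree, records, ontology, go_id,
                                 config = evidence_config()) {
  leaves <- tree$nodes$node_id[tree$nodes$is_leaf]
  usable_codes <- config$experimental_codes
  if (config$htp_usable_for_inference) usable_codes <- c(usable_codes, config$htp_codes)
  pos_terms <- c(go_id, oracle_descendants(ontology, go_id))
  neg_terms <- c(go_id, oracle_ancestors(ontology, go_id))
  P <- character(); N <- character()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!(r$object_id %in% leaves)) next
    if (!(r$evidence_code %in% usable_codes)) next
    if (!r$negated && r$go_id %in% pos_terms) P <- c(P, r$object_id)
    if (r$negated && r$go_id %in% neg_terms) N <- c(N, r$object_id)
  }
  P <- sort(unique(P))
  N <- sort(unique(setdiff(N, P)))
  list(P = P, N = N)
}
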