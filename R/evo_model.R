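#' Construct an evolutionary gain/loss model
#'
#' An explicit, curator-style model of the evolution of one or more
#' functions on a gene family tree: each gain asserts that a function first
#' evolved at a given ancestral node (supported by experimentally
#' characterized descendant genes), and each loss asserts that the function
#' was subsequently lost along a descendant lineage. Annotation follows the
#' Dollo convention: a function is gained once per lineage and may be lost
#' many times.
#'
#' @param family_id Family identifier.
#' @param gains Tibble with columns `node_id`, `go_id`,
#'   `supporting_leaves` (list of character vectors of leaf ids), and
#'   optionally `references` (list of character vectors).
#' @param losses Tibble with columns `node_id`, `go_id`, `cause`
#'   (`KEY_RESIDUES`, `RAPID_DIVERGENCE` or `UNSPECIFIED`).
#' @return An object of class `evolutionary_model`.
#' @seealso [validate_model()], [propagate()], [suggest_model()]
#' @export
evolutionary_model <- function(family_id, gains = NULL, losses = NULL) {
  empty_gains <- tibble(node_id = character(), go_id = character(),
                        supporting_leaves = list(), references = list())
  empty_losses <- tibble(node_id = character(), go_id = character(),
                         cause = character())
  gains <- if (is.null(gains) || nrow(gains) == 0) empty_gains else {
    g <- as_tibble(gains)
    if (!"references" %in% names(g)) g$references <- rep(list(character()), nrow(g))
    g[, names(empty_gains)]
  }
  losses <- if (is.null(losses) || nrow(losses) == 0) empty_losses else
    as_tibble(losses)[, names(empty_losses)]
  bad <- setdiff(losses$cause, loss_causes)
  if (length(bad)) {
    abort(sprintf("unknown loss cause(s): %s", paste(bad, collapse = ", ")),
          class = "phyloanno_enum_error")
  }
  structure(list(family_id = family_id, gains = gains, losses = losses),
            class = "evolutionary_model")
}

loss_causes <- c("KEY_RESIDUES", "RAPID_DIVERGENCE", "UNSPECIFIED")
loss_evidence <- c(KEY_RESIDUES = "IKR", RAPID_DIVERGENCE = "IRD",
                   UNSPECIFIED = "IKR")

#' @export
print.evolutionary_model <- function(x, ...) {
  cat(sprintf("<evolutionary_model> family %s: %d gain(s), %d loss(es)\n",
              x$family_id, nrow(x$gains), nrow(x$losses)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evolutionary model into one row per event
#'
#' @param x An `evolutionary_model`.
#' @param ... Ignored.
#' @return Tibble with columns `event`, `node_id`, `go_id`, `n_support`,
#'   `cause`.
#' @exportS3Method generics::tidy
tidy.evolutionary_model <- function(x, ...) {
  bind_rows(
    tibble(event = rep("gain", nrow(x$gains)), node_id = x$gains$node_id,
           go_id = x$gains$go_id,
           n_support = lengths(x$gains$supporting_leaves),
           cause = NA_character_),
    tibble(event = rep("loss", nrow(x$losses)), node_id = x$losses$node_id,
           go_id = x$losses$go_id, n_support = NA_integer_,
           cause = x$losses$cause)
  )
}

#' One-row summary of an evolutionary model
#'
#' @param x An `evolutionary_model`.
#' @param ... Ignored.
#' @return Tibble with `family_id`, `n_gains`, `n_losses`, `n_terms`,
#'   `n_supporting_leaves`.
#' @exportS3Method generics::glance
glance.evolutionary_model <- function(x, ...) {
  tibble(family_id = x$family_id, n_gains = nrow(x$gains),
         n_losses = nrow(x$losses),
         n_terms = n_distinct(c(x$gains$go_id, character())),
         n_supporting_leaves =
           n_distinct(unlist(x$gains$supporting_leaves, use.names = FALSE)))
}

#' Parse a curator assertion file
#'
#' The assertion format is the on-disk serialization of the curator's
#' gain/loss model, one event per line:
#' \preformatted{GAIN  <node>  <GO id>  <leaf,leaf,...>
#' LOSS  <node>  <GO id>  <cause>}
#' Fields are tab- (or whitespace-) separated; `#` starts a comment.
#' Terms are resolved through [resolve_term()]: an obsolete term with a
#' replacement is rewritten (and the rewrite reported via a message); an
#' obsolete term without one is an error.
#'
#' @param x Path or document text.
#' @param tree The family `gene_tree` (nodes and support leaves are checked
#'   against it).
#' @param ontology An `ontology_graph`.
#' @return An `evolutionary_model`.
#' @export
parse_assertions <- function(x, tree, ontology) {
  lines <- input_lines(x)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  gains <- list()
  losses <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 4) {
      abort(sprintf("assertion line %d: expected 4 fields, got %d", i, length(f)),
            class = "phyloanno_parse_error")
    }
    kind <- f[1]; node <- f[2]; term <- f[3]
    if (!(node %in% tree$nodes$node_id) && !(node %in% tree$nodes$gene_id)) {
      abort(sprintf("assertion line %d: unknown node %s", i, node),
            class = "phyloanno_reference_error")
    }
    node <- resolve_node(tree, node)
    if (!(term %in% ontology$terms$id)) {
      abort(sprintf("assertion line %d: unknown term %s", i, term),
            class = "phyloanno_reference_error")
    }
    resolved <- resolve_term(ontology, term)
    if (!identical(resolved, term)) {
      inform(sprintf("assertion line %d: obsolete term %s rewritten to %s",
                     i, term, resolved))
      term <- resolved
    }
    if (kind == "GAIN") {
      leaves <- strsplit(f[4], ",", fixed = TRUE)[[1]]
      leaves <- vapply(leaves, function(l) {
        if (!(l %in% tree$nodes$node_id) && !(l %in% tree$nodes$gene_id)) {
          abort(sprintf("assertion line %d: unknown leaf %s", i, l),
                class = "phyloanno_reference_error")
        }
        resolve_node(tree, l)
      }, character(1), USE.NAMES = FALSE)
      not_below <- leaves[!vapply(leaves, function(l) is_ancestor(tree, node, l),
                                  logical(1))]
      if (length(not_below)) {
        abort(sprintf(
          "assertion line %d: gain node %s is not ancestral to support leaf %s",
          i, node, paste(not_below, collapse = ", ")),
          class = "phyloanno_reference_error")
      }
      gains[[length(gains) + 1L]] <- tibble(
        node_id = node, go_id = term,
        supporting_leaves = list(sort(leaves)), references = list(character()))
    } else if (kind == "LOSS") {
      cause <- f[4]
      if (!(cause %in% loss_causes)) {
        abort(sprintf("assertion line %d: unknown loss cause %s", i, cause),
              class = "phyloanno_enum_error")
      }
      losses[[length(losses) + 1L]] <- tibble(node_id = node, go_id = term,
                                              cause = cause)
    } else {
      abort(sprintf("assertion line %d: unknown assertion kind %s", i, kind),
            class = "phyloanno_parse_error")
    }
  }
  evolutionary_model(tree$family_id,
                     if (length(gains)) bind_rows(gains) else NULL,
                     if (length(losses)) bind_rows(losses) else NULL)
}

#' Serialize an evolutionary model to the assertion format
#'
#' @param model An `evolutionary_model`.
#' @param file Optional output path.
#' @return The document as a string, invisibly when `file` is set.
#' @export
write_assertions <- function(model, file = NULL) {
  g <- model$gains[order(model$gains$go_id, model$gains$node_id), , drop = FALSE]
  l <- model$losses[order(model$losses$go_id, model$losses$node_id), , drop = FALSE]
  lines <- c(
    sprintf("# family: %s", model$family_id),
    if (nrow(g)) paste("GAIN", g$node_id, g$go_id,
                       vapply(g$supporting_leaves, paste, character(1),
                              collapse = ","), sep = "\t"),
    if (nrow(l)) paste("LOSS", l$node_id, l$go_id, l$cause, sep = "\t")
  )
  if (!is.null(file)) {
    write_lines_file(lines, file)
    return(invisible(paste(lines, collapse = "\n")))
  }
  paste(lines, collapse = "\n")
}

# does a loss of term t_loss block (apply to) a gain of term t_gain?
# Losing a general capability entails losing its specializations, so the
# loss term must be the gain term itself or an ontology ancestor of it.
loss_blocks_term <- function(ontology, t_loss, t_gain) {
  t_loss == t_gain || t_loss %in% go_ancestors(ontology, t_gain)
}

#' Validate an evolutionary model against tree, ontology and evidence
#'
#' A model is consistent when: every gain node dominates all its supporting
#' leaves; every supporting leaf carries at least one usable experimental
#' record to the gain term or an ontology descendant of it (the true-path
#' rule — evidence for a specialization is evidence for the general term);
#' every loss lies strictly below a gain it blocks (same term, or the loss
#' term is an ontology ancestor of the gain term); and no two gains of the
#' same term are nested (a function is gained once per lineage; independent
#' gains on disjoint lineages are allowed).
#'
#' @param model An `evolutionary_model`.
#' @param tree A `gene_tree`.
#' @param ontology An `ontology_graph`.
#' @param usable_records Usable experimental records (the `usable` element
#'   of [filter_experimental()]), or `NULL` to skip the evidence check
#'   (structural validation only).
#' @return Tibble of violations with columns `rule`, `node_id`, `go_id`,
#'   `detail`; zero rows means the model is valid. Violations are data,
#'   not exceptions.
#' @export
validate_model <- function(model, tree, ontology, usable_records = NULL) {
  v <- list()
  bad <- function(rule, node_id, go_id, detail) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, node_id = node_id,
                                   go_id = go_id, detail = detail)
  }
  g <- model$gains
  l <- model$losses
  known_node <- function(id) id %in% tree$nodes$node_id || id %in% tree$nodes$gene_id

  for (i in seq_len(nrow(g))) {
    if (!known_node(g$node_id[i])) {
      bad("unknown_node", g$node_id[i], g$go_id[i], "gain node not in tree")
      next
    }
    if (!(g$go_id[i] %in% ontology$terms$id)) {
      bad("unknown_term", g$node_id[i], g$go_id[i], "gain term not in ontology")
      next
    }
    leaves <- g$supporting_leaves[[i]]
    if (length(leaves) == 0) {
      bad("unsupported_gain", g$node_id[i], g$go_id[i], "no supporting leaves")
      next
    }
    missing <- leaves[!vapply(leaves, known_node, logical(1))]
    if (length(missing)) {
      bad("unknown_leaf", g$node_id[i], g$go_id[i],
          paste("unknown support leaf:", paste(missing, collapse = ", ")))
      next
    }
    above <- vapply(leaves, function(x) is_ancestor(tree, g$node_id[i], x),
                    logical(1))
    if (!all(above)) {
      bad("gain_not_ancestral", g$node_id[i], g$go_id[i],
          paste("support outside subtree:",
                paste(leaves[!above], collapse = ", ")))
    }
    if (!is.null(usable_records)) {
      ok_terms <- go_descendants(ontology, g$go_id[i], reflexive = TRUE)
      unsupported <- leaves[!vapply(leaves, function(leaf) {
        any(usable_records$object_id == leaf &
              usable_records$go_id %in% ok_terms)
      }, logical(1))]
      if (length(unsupported)) {
        bad("unsupported_gain", g$node_id[i], g$go_id[i],
            paste("no usable experimental record for:",
                  paste(unsupported, collapse = ", ")))
      }
    }
  }

  for (i in seq_len(nrow(l))) {
    if (!known_node(l$node_id[i])) {
      bad("unknown_node", l$node_id[i], l$go_id[i], "loss node not in tree")
      next
    }
    if (!(l$go_id[i] %in% ontology$terms$id)) {
      bad("unknown_term", l$node_id[i], l$go_id[i], "loss term not in ontology")
      next
    }
    matched <- FALSE
    for (j in seq_len(nrow(g))) {
      if (!known_node(g$node_id[j]) || !(g$go_id[j] %in% ontology$terms$id)) next
      if (g$node_id[j] != l$node_id[i] &&
          is_ancestor(tree, g$node_id[j], l$node_id[i]) &&
          loss_blocks_term(ontology, l$go_id[i], g$go_id[j])) {
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      bad("loss_without_gain", l$node_id[i], l$go_id[i],
          "loss is not strictly below any gain it blocks")
    }
  }

  if (nrow(g) > 1) {
    for (i in seq_len(nrow(g) - 1)) {
      for (j in seq(i + 1, nrow(g))) {
        if (g$go_id[i] == g$go_id[j] &&
            known_node(g$node_id[i]) && known_node(g$node_id[j]) &&
            (is_ancestor(tree, g$node_id[i], g$node_id[j]) ||
             is_ancestor(tree, g$node_id[j], g$node_id[i]))) {
          bad("nested_gain", g$node_id[j], g$go_id[j],
              paste("nested with gain at", g$node_id[i]))
        }
      }
    }
  }

  if (length(v)) bind_rows(v) else
    tibble(rule = character(), node_id = character(), go_id = character(),
           detail = character())
}

#' Experimental presence and negation sets for a term
#'
#' Gathers, for one GO term, the leaves that carry usable experimental
#' evidence *for* the function (`P`) and those carrying negated
#' experimental evidence *against* it (`N`). The true-path rule works in
#' both directions: a positive record to the term or any ontology
#' descendant puts a leaf in `P` (evidence for a specialization is evidence
#' for the general function), while a NOT record to the term or any
#' ontology *ancestor* puts it in `N` (lacking a general capability entails
#' lacking its specializations). A leaf with both kinds of evidence is
#' assigned to `P` and reported in `conflicts`.
#'
#' @param tree A `gene_tree`.
#' @param records A GAF record tibble (filtering is applied internally).
#' @param ontology An `ontology_graph`.
#' @param go_id The query term.
#' @param config An [evidence_config()].
#' @return A list with character vectors `P`, `N`, `conflicts`, and the
#'   query `go_id`.
#' @export
presence_sets <- function(tree, records, ontology, go_id,
                          config = evidence_config()) {
  check_term(ontology, go_id)
  filt <- filter_experimental(records, config)
  leaf_ids <- tree_leaf_ids(tree)
  pos_terms <- go_descendants(ontology, go_id, reflexive = TRUE)
  neg_terms <- go_ancestors(ontology, go_id, reflexive = TRUE)
  u <- filt$usable
  P <- sort(unique(u$object_id[u$object_id %in% leaf_ids &
                                 u$go_id %in% pos_terms]))
  neg <- filt$excluded[filt$excluded$exclusion_reason == "negated", , drop = FALSE]
  N <- sort(unique(neg$object_id[neg$object_id %in% leaf_ids &
                                   neg$go_id %in% neg_terms]))
  conflicts <- intersect(P, N)
  N <- setdiff(N, P)
  if (length(conflicts)) {
    warn(sprintf("leaf/leaves with conflicting evidence for %s assigned to P: %s",
                 go_id, paste(conflicts, collapse = ", ")))
  }
  list(P = P, N = N, conflicts = conflicts, go_id = go_id)
}

#' Suggest a Dollo-parsimonious gain/loss model for one term
#'
#' Single-gain Dollo suggestion: the gain is anchored at the most recent
#' common ancestor of the leaves with positive experimental evidence — the
#' most recent point at which the function can have evolved once and still
#' be inherited by every supported gene. Losses are placed only where
#' negative evidence demands them: at the maximal (closest to the gain)
#' subtrees that contain at least one negatively evidenced leaf and no
#' positively evidenced leaf. Absence of annotation is never treated as
#' absence of function; the resulting loss set is provably
#' minimum-cardinality among loss sets that exclude all of `N` below the
#' gain and none of `P`.
#'
#' @param tree A `gene_tree`.
#' @param P Character vector of leaves with positive experimental evidence
#'   (nonempty).
#' @param N Character vector of leaves with negated experimental evidence.
#' @param go_id The function's GO term.
#' @param family_id Family identifier (defaults to the tree's).
#' @return A list of class `model_suggestion` with elements `model` (an
#'   `evolutionary_model` whose losses carry cause `UNSPECIFIED`),
#'   `alternates` (ancestors of the suggested gain node, nearest first —
#'   legal but less parsimonious gain points), and `single_support`
#'   (`TRUE` when `|P| = 1`: such a gain is legal but flagged, because
#'   propagation from a single characterized gene is weak evidence of
#'   conservation).
#' @export
suggest_model <- function(tree, P, N = character(), go_id,
                          family_id = tree$family_id) {
  if (length(P) == 0) {
    abort("no experimental evidence: P is empty",
          class = "phyloanno_no_evidence")
  }
  P <- vapply(P, function(x) resolve_node(tree, x), character(1),
              USE.NAMES = FALSE)
  N <- vapply(N, function(x) resolve_node(tree, x), character(1),
              USE.NAMES = FALSE)
  g <- tree_mrca(tree, P)
  kids <- tree_children_map(tree)
  below <- tree_descendants(tree, g)
  loss_nodes <- character()
  if (length(N)) {
    cand <- vapply(below, function(v) {
      lv <- leaves_under(tree, v, kids)
      !any(lv %in% P) && any(lv %in% N)
    }, logical(1))
    parents <- stats::setNames(tree$nodes$parent, tree$nodes$node_id)
    is_cand <- stats::setNames(cand, below)
    maximal <- below[cand & vapply(below, function(v) {
      p <- parents[[v]]
      identical(p, g) || !isTRUE(is_cand[[p]])
    }, logical(1))]
    loss_nodes <- maximal
  }
  model <- evolutionary_model(
    family_id,
    gains = tibble(node_id = g, go_id = go_id,
                   supporting_leaves = list(sort(unique(P))),
                   references = list(character())),
    losses = if (length(loss_nodes)) {
      tibble(node_id = loss_nodes, go_id = go_id, cause = "UNSPECIFIED")
    } else NULL
  )
  alternates <- setdiff(path_to_root(tree, g), g)
  structure(list(model = model, alternates = alternates,
                 single_support = length(unique(P)) == 1),
            class = "model_suggestion")
}

#' @export
print.model_suggestion <- function(x, ...) {
  g <- x$model$gains
  cat(sprintf("<model_suggestion> gain %s at %s (%d supporting leaves)%s\n",
              g$go_id[1], g$node_id[1], lengths(g$supporting_leaves)[1],
              if (x$single_support) " [single-support]" else ""))
  if (nrow(x$model$losses)) {
    cat("  losses:", paste(x$model$losses$node_id, collapse = ", "), "\n")
  }
  if (length(x$alternates)) {
    cat("  less parsimonious gain points:",
        paste(x$alternates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Propagate a validated model over the tree
#'
#' Step two of the annotation process: the explicit gain/loss model is
#' applied to create inferred annotations over the entire tree. Each gain
#' `(g, t)` yields one IBD annotation ("inferred from biological
#' descendant") at `g` and one IBA annotation ("inferred from biological
#' ancestor") at every strict descendant of `g` outside any blocked
#' subtree. A loss `(v, t')` blocks the subtree rooted at `v` for every
#' gain term that is `t'` or an ontology descendant of `t'`, and yields a
#' negated annotation at `v` itself with evidence IKR (cause
#' `KEY_RESIDUES` or `UNSPECIFIED`) or IRD (`RAPID_DIVERGENCE`). Every
#' IBD/IBA row carries its gain node and the supporting experimental
#' leaves, so the provenance of each inferred annotation is explicit.
#' Leaves that already have experimental records still receive IBA.
#' Duplication nodes do not block propagation; IBA rows whose lineage
#' passes through a horizontal-transfer node are tagged `via_hgt`.
#'
#' @param model An `evolutionary_model`; it must validate cleanly
#'   (structurally, plus against `records` when supplied), otherwise the
#'   call is rejected with the violations attached to the condition.
#' @param tree A `gene_tree`.
#' @param ontology An `ontology_graph`.
#' @param records Optional GAF records for the evidence-level validation.
#' @param config An [evidence_config()] (used only with `records`).
#' @return A tibble of class `inferred_annotations`, ordered by (gain term,
#'   target preorder index), with columns `target`, `go_id`, `evidence`
#'   (IBD/IBA/IKR/IRD), `negated`, `cause`, `gain_node`,
#'   `supporting_leaves` (list), `is_leaf`, `gene_id`, `species`,
#'   `via_hgt`.
#' @export
propagate <- function(model, tree, ontology, records = NULL,
                      config = evidence_config()) {
  usable <- if (!is.null(records)) filter_experimental(records, config)$usable
  violations <- validate_model(model, tree, ontology, usable)
  if (nrow(violations)) {
    abort(sprintf("invalid model: %d violation(s); first: %s (%s at %s)",
                  nrow(violations), violations$rule[1], violations$go_id[1],
                  violations$node_id[1]),
          class = "phyloanno_invalid_model", violations = violations)
  }

  n <- tree$nodes
  kids <- tree_children_map(tree)
  pre <- stats::setNames(n$preorder, n$node_id)
  depth <- node_depths(tree)
  info <- function(ids) {
    m <- match(ids, n$node_id)
    list(is_leaf = n$is_leaf[m], gene_id = n$gene_id[m], species = n$species[m])
  }
  hgt_nodes <- n$node_id[n$event == "horizontal_transfer"]

  g <- model$gains
  ord <- order(g$go_id, pre[g$node_id])
  g <- g[ord, , drop = FALSE]
  l <- model$losses
  emitted_losses <- character(0)  # "node_id\034go_id" keys already emitted
  out <- list()

  for (i in seq_len(nrow(g))) {
    gnode <- g$node_id[i]; gterm <- g$go_id[i]
    support <- g$supporting_leaves[[i]]
    desc <- descend_from(kids, gnode)

    match_loss <- logical(nrow(l))
    for (j in seq_len(nrow(l))) {
      match_loss[j] <- l$node_id[j] %in% desc &&
        loss_blocks_term(ontology, l$go_id[j], gterm)
    }
    blocked <- character()
    for (j in which(match_loss)) {
      blocked <- union(blocked, c(l$node_id[j], descend_from(kids, l$node_id[j])))
    }

    # via-HGT tagging: a target is tagged when its lineage from the gain
    # node (exclusive) down to and including itself crosses an HGT node
    via <- stats::setNames(logical(length(desc)), desc)
    for (v in desc) {
      p <- n$parent[match(v, n$node_id)]
      via[[v]] <- (v %in% hgt_nodes) ||
        (!identical(p, gnode) && isTRUE(via[[p]]))
    }

    ibd_i <- info(gnode)
    out[[length(out) + 1L]] <- tibble(
      target = gnode, go_id = gterm, evidence = "IBD", negated = FALSE,
      cause = NA_character_, gain_node = gnode,
      supporting_leaves = list(support), is_leaf = ibd_i$is_leaf,
      gene_id = ibd_i$gene_id, species = ibd_i$species, via_hgt = FALSE)

    iba_targets <- setdiff(desc, blocked)
    iba_targets <- iba_targets[order(pre[iba_targets])]
    if (length(iba_targets)) {
      ii <- info(iba_targets)
      out[[length(out) + 1L]] <- tibble(
        target = iba_targets, go_id = gterm, evidence = "IBA", negated = FALSE,
        cause = NA_character_, gain_node = gnode,
        supporting_leaves = rep(list(support), length(iba_targets)),
        is_leaf = ii$is_leaf, gene_id = ii$gene_id, species = ii$species,
        via_hgt = as.logical(via[iba_targets]))
    }

    for (j in which(match_loss)) {
      key <- paste(l$node_id[j], l$go_id[j], sep = "\034")
      if (key %in% emitted_losses) next
      emitted_losses <- c(emitted_losses, key)
      li <- info(l$node_id[j])
      out[[length(out) + 1L]] <- tibble(
        target = l$node_id[j], go_id = l$go_id[j],
        evidence = unname(loss_evidence[l$cause[j]]), negated = TRUE,
        cause = l$cause[j], gain_node = gnode,
        supporting_leaves = list(character()), is_leaf = li$is_leaf,
        gene_id = li$gene_id, species = li$species,
        via_hgt = as.logical(via[[l$node_id[j]]]))
    }
  }

  res <- if (length(out)) bind_rows(out) else tibble(
    target = character(), go_id = character(), evidence = character(),
    negated = logical(), cause = character(), gain_node = character(),
    supporting_leaves = list(), is_leaf = logical(), gene_id = character(),
    species = character(), via_hgt = logical())
  class(res) <- c("inferred_annotations", class(res))
  res
}

#' One-row summary of inferred annotations
#'
#' @param x An `inferred_annotations` tibble.
#' @param ... Ignored.
#' @return Tibble with counts of IBD, IBA and negated loss (IKR/IRD)
#'   annotations, the number of distinct leaf proteins receiving IBA and
#'   distinct inferred terms.
#' @exportS3Method generics::glance
glance.inferred_annotations <- function(x, ...) {
  tibble(
    n_ibd = sum(x$evidence == "IBD"),
    n_iba = sum(x$evidence == "IBA"),
    n_loss = sum(x$evidence %in% c("IKR", "IRD")),
    n_iba_proteins = n_distinct(x$target[x$evidence == "IBA" & x$is_leaf]),
    n_terms = n_distinct(x$go_id[x$evidence == "IBD"])
  )
}

#' Detect conflicts between inferred annotations and experimental records
#'
#' Two conflict patterns are reported (conflicts are findings for curator
#' review, not errors): an IBA landing on a leaf that holds a negated
#' experimental record to the same term or an ontology ancestor of it
#' (negative evidence under propagation); and a leaf inside a blocked
#' (loss) subtree that holds a usable positive record to the lost term or
#' an ontology descendant of it (experimental evidence under loss).
#'
#' @param inferred Output of [propagate()].
#' @param records GAF records.
#' @param tree A `gene_tree` (needed to enumerate blocked-subtree leaves).
#' @param model The `evolutionary_model` behind `inferred`.
#' @param ontology An `ontology_graph`.
#' @param config An [evidence_config()].
#' @return Tibble with columns `rule`, `leaf`, `go_id`, `evidence_go_id`,
#'   `detail`.
#' @export
detect_conflicts <- function(inferred, records, tree, model, ontology,
                             config = evidence_config()) {
  filt <- filter_experimental(records, config)
  neg <- filt$excluded[filt$excluded$exclusion_reason == "negated", , drop = FALSE]
  out <- list()

  iba_leaf <- inferred[inferred$evidence == "IBA" & inferred$is_leaf, ,
                       drop = FALSE]
  for (i in seq_len(nrow(iba_leaf))) {
    anc <- go_ancestors(ontology, iba_leaf$go_id[i], reflexive = TRUE)
    hits <- neg[neg$object_id == iba_leaf$target[i] & neg$go_id %in% anc, ,
                drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      out[[length(out) + 1L]] <- tibble(
        rule = "negative_evidence_under_propagation",
        leaf = iba_leaf$target[i], go_id = iba_leaf$go_id[i],
        evidence_go_id = hits$go_id[j],
        detail = sprintf("IBA to %s but leaf has NOT-%s record to %s",
                         iba_leaf$go_id[i], hits$evidence_code[j],
                         hits$go_id[j]))
    }
  }

  u <- filt$usable
  for (j in seq_len(nrow(model$losses))) {
    lv <- leaves_under(tree, model$losses$node_id[j])
    dsc <- go_descendants(ontology, model$losses$go_id[j], reflexive = TRUE)
    hits <- u[u$object_id %in% lv & u$go_id %in% dsc, , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      out[[length(out) + 1L]] <- tibble(
        rule = "experimental_evidence_under_loss",
        leaf = hits$object_id[k], go_id = model$losses$go_id[j],
        evidence_go_id = hits$go_id[k],
        detail = sprintf("loss of %s at %s but leaf has %s record to %s",
                         model$losses$go_id[j], model$losses$node_id[j],
                         hits$evidence_code[k], hits$go_id[k]))
    }
  }
  if (length(out)) distinct(bind_rows(out)) else
    tibble(rule = character(), leaf = character(), go_id = character(),
           evidence_go_id = character(), detail = character())
}

#' Export inferred annotations as GAF records
#'
#' Maps inferred annotations onto the standard GAF encoding used for
#' phylogenetic annotation: IBD rows describe ancestral nodes
#' (`db = "PANTHER"`, `object_id = "<family>:<node>"`) with the supporting
#' experimental gene ids in `with/from`; IBA rows on extant genes carry a
#' pointer back to their gain node (`PANTHER:<family>:<gain node>`)
#' followed by the supporting gene ids; loss rows use evidence IKR/IRD with
#' a NOT qualifier. All rows cite reference `GO_REF:0000033` (annotation
#' inferred from phylogenetic evidence).
#'
#' @param inferred Output of [propagate()].
#' @param tree The family `gene_tree`.
#' @param ontology An `ontology_graph` (for the aspect column).
#' @param assigned_by Value for the `assigned_by` column.
#' @param date Annotation date, `YYYYMMDD`.
#' @return A GAF record tibble suitable for [write_gaf()].
#' @export
inferred_to_gaf <- function(inferred, tree, ontology,
                            assigned_by = "phylo-annot",
                            date = format(Sys.Date(), "%Y%m%d")) {
  if (nrow(inferred) == 0) return(empty_gaf())
  fam <- tree$family_id
  ns_letter <- c(molecular_function = "F", biological_process = "P",
                 cellular_component = "C")
  ns <- ontology$terms$namespace[match(inferred$go_id, ontology$terms$id)]
  aspect <- unname(ns_letter[ns])
  aspect[is.na(aspect)] <- "P"

  leaf_gene <- stats::setNames(tree$nodes$gene_id, tree$nodes$node_id)

  rows <- lapply(seq_len(nrow(inferred)), function(i) {
    r <- inferred[i, ]
    leaf <- isTRUE(r$is_leaf)
    db <- if (leaf) sub(":.*$", "", r$gene_id) else "PANTHER"
    oid <- if (leaf) r$target else paste(fam, r$target, sep = ":")
    support <- unname(leaf_gene[setdiff(r$supporting_leaves[[1]], r$target)])
    support <- support[!is.na(support)]
    wf <- if (r$evidence == "IBD") {
      support
    } else {
      c(paste("PANTHER", fam, r$gain_node, sep = ":"), support)
    }
    gaf_record(
      db = db, object_id = oid, go_id = r$go_id,
      evidence_code = r$evidence, symbol = r$target,
      qualifier = if (r$negated) "NOT" else "",
      references = list("GO_REF:0000033"), with_from = list(wf),
      aspect = aspect[i],
      taxon = if (leaf && !is.na(r$species)) paste0("taxon:", r$species)
              else "taxon:root",
      date = date, assigned_by = assigned_by)
  })
  bind_rows(rows)
}
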