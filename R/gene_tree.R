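#' Parse a gene family tree in NHX-tagged Newick
#'
#' Reads a single rooted Newick tree whose nodes may carry NHX comment tags:
#' `ID=<node id>`, `Ev=<S|D|H>` (speciation / duplication / horizontal
#' transfer) and `S=<species code>`. Leaf labels are database-qualified gene
#' accessions of the form `DB:ACC`; the accession doubles as the leaf's
#' stable node id unless an explicit `ID` tag overrides it. Internal nodes
#' without an `ID` tag receive generated ids `AN<k>` where `k` is the node's
#' preorder position (root = 0); internals without an `Ev` tag default to
#' speciation. Branch lengths are parsed and preserved but ignored by the
#' gain/loss machinery, which is event-based rather than clock-based.
#'
#' @param x Path to a Newick/NHX file, or the document itself.
#' @param family_id Family identifier (e.g. a PANTHER id such as
#'   `"PTHR10454"`).
#' @return An object of class `gene_tree`: a list with `family_id` and
#'   `nodes`, a tibble in preorder with columns `node_id`, `parent`, `event`,
#'   `species`, `gene_id`, `branch_length`, `is_leaf`, `preorder`.
#' @details Polytomies (>= 2 children) are accepted; a one-child internal
#'   node, a leaf without a `DB:ACC` accession, duplicate node ids, and
#'   unbalanced parentheses are errors. The tree must be rooted: gain/loss
#'   direction is meaningless without a root.
#' @seealso [write_tree()], [tree_mrca()], [tree_descendants()]
#' @export
parse_tree <- function(x, family_id = "FAM") {
  s <- gsub("[[:space:]]+", "", input_text(x))
  if (!nzchar(s)) abort("empty tree input", class = "phyloanno_parse_error")
  pos <- 1L
  nlen <- nchar(s)
  peek <- function() substr(s, pos, pos)
  read_until <- function(stopre) {
    rest <- substr(s, pos, nlen)
    m <- regexpr(stopre, rest)
    if (m == -1L) {
      pos <<- nlen + 1L
      rest
    } else {
      pos <<- pos + m - 1L
      substr(rest, 1, m - 1L)
    }
  }

  parse_comment <- function() {
    # pos is at '['
    rest <- substr(s, pos, nlen)
    close <- regexpr("]", rest, fixed = TRUE)
    if (close == -1L) {
      abort(sprintf("unterminated comment at position %d", pos),
            class = "phyloanno_parse_error")
    }
    content <- substr(rest, 2, close - 1L)
    pos <<- pos + close
    if (!startsWith(content, "&&NHX")) return(NULL)
    kvs <- strsplit(sub("^&&NHX:?", "", content), ":", fixed = TRUE)[[1]]
    kvs <- kvs[nzchar(kvs)]
    if (!length(kvs)) return(NULL)
    pairs <- strsplit(kvs, "=", fixed = TRUE)
    vals <- vapply(pairs, function(p) if (length(p) >= 2) p[2] else "", character(1))
    names(vals) <- vapply(pairs, `[`, character(1), 1)
    vals
  }

  split_branch <- function(chunk) {
    m <- regmatches(chunk, regexec("^(.*?):([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)$", chunk))[[1]]
    if (length(m)) list(label = m[2], blen = as.numeric(m[3]))
    else list(label = chunk, blen = NA_real_)
  }

  parse_node <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        abort(sprintf("unbalanced parentheses near position %d", pos),
              class = "phyloanno_parse_error")
      }
    }
    chunk <- read_until("[(),;\\[]")
    nhx <- NULL
    if (peek() == "[") nhx <- parse_comment()
    # a branch length may also follow the comment
    chunk2 <- read_until("[(),;\\[]")
    sb <- split_branch(paste0(chunk, chunk2))
    list(children = children, label = sb$label, blen = sb$blen, nhx = nhx)
  }

  root <- parse_node()
  if (peek() == ";") pos <- pos + 1L
  if (pos <= nlen) {
    abort(sprintf("trailing content after tree at position %d", pos),
          class = "phyloanno_parse_error")
  }

  ev_map <- c(S = "speciation", D = "duplication", H = "horizontal_transfer")
  rows <- list()
  emit <- function(node, parent_id, idx) {
    # idx: environment carrying the preorder counter
    my_pre <- idx$k
    idx$k <- idx$k + 1L
    nhx <- node$nhx
    is_leaf <- length(node$children) == 0
    if (!is_leaf && length(node$children) == 1) {
      abort("internal node with a single child is not allowed",
            class = "phyloanno_structure_error")
    }
    if (is_leaf) {
      if (!nzchar(node$label) || !grepl(":", node$label, fixed = TRUE)) {
        abort(sprintf("leaf without database-qualified accession (got '%s')",
                      node$label),
              class = "phyloanno_structure_error")
      }
      acc <- sub("^[^:]*:", "", node$label)
      node_id <- if (!is.null(nhx) && "ID" %in% names(nhx)) nhx[["ID"]] else acc
      event <- "leaf"
      gene_id <- node$label
    } else {
      node_id <- if (!is.null(nhx) && "ID" %in% names(nhx)) nhx[["ID"]]
                 else sprintf("AN%d", my_pre)
      ev <- if (!is.null(nhx) && "Ev" %in% names(nhx)) nhx[["Ev"]] else "S"
      if (!(ev %in% names(ev_map))) {
        abort(sprintf("unknown event code '%s' at node %s", ev, node_id),
              class = "phyloanno_parse_error")
      }
      event <- ev_map[[ev]]
      gene_id <- NA_character_
    }
    species <- if (!is.null(nhx) && "S" %in% names(nhx)) nhx[["S"]] else NA_character_
    rows[[length(rows) + 1L]] <<- tibble(
      node_id = node_id, parent = parent_id, event = event,
      species = species, gene_id = gene_id, branch_length = node$blen,
      is_leaf = is_leaf, preorder = my_pre
    )
    for (ch in node$children) emit(ch, node_id, idx)
  }
  idx <- new.env()
  idx$k <- 0L
  emit(root, NA_character_, idx)
  nodes <- bind_rows(rows)
  if (anyDuplicated(nodes$node_id)) {
    abort(sprintf("duplicate node id(s): %s",
                  paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
                        collapse = ", ")),
          class = "phyloanno_structure_error")
  }
  new_gene_tree(family_id, nodes)
}

new_gene_tree <- function(family_id, nodes) {
  leaves <- nodes[nodes$is_leaf, , drop = FALSE]
  if (anyDuplicated(leaves$gene_id)) {
    abort("duplicate leaf gene accessions", class = "phyloanno_structure_error")
  }
  structure(list(family_id = family_id, nodes = as_tibble(nodes)),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> family %s: %d nodes (%d leaves)\n",
              x$family_id, nrow(x$nodes), sum(x$nodes$is_leaf)))
  invisible(x)
}

#' Serialize a gene tree to NHX-tagged Newick
#'
#' Deterministic writer: NHX keys in sorted order (`Ev`, `ID`, `S`), branch
#' lengths with 6 decimals, children in stored (preorder) order, so that
#' `parse_tree(write_tree(t), t$family_id)` reproduces the tree exactly.
#'
#' @param tree A `gene_tree`.
#' @param file Optional output path.
#' @return The Newick document as a string, invisibly when `file` is set.
#' @export
write_tree <- function(tree, file = NULL) {
  nodes <- tree$nodes
  kids <- tree_children_map(tree)
  ev_code <- c(speciation = "S", duplication = "D", horizontal_transfer = "H")
  fmt <- function(node_id) {
    row <- nodes[match(node_id, nodes$node_id), ]
    tags <- character()
    if (row$is_leaf) {
      label <- row$gene_id
      acc <- sub("^[^:]*:", "", row$gene_id)
      if (!identical(row$node_id, acc)) tags <- c(tags, paste0("ID=", row$node_id))
    } else {
      label <- ""
      tags <- c(tags, paste0("Ev=", ev_code[[row$event]]), paste0("ID=", row$node_id))
    }
    if (!is.na(row$species)) tags <- c(tags, paste0("S=", row$species))
    tags <- tags[order(sub("=.*$", "", tags))]
    nhx <- if (length(tags)) paste0("[&&NHX:", paste(tags, collapse = ":"), "]") else ""
    blen <- if (is.na(row$branch_length)) "" else sprintf(":%.6f", row$branch_length)
    inner <- if (row$is_leaf) "" else
      paste0("(", paste(vapply(kids[[node_id]], fmt, character(1)), collapse = ","), ")")
    paste0(inner, label, blen, nhx)
  }
  root <- nodes$node_id[is.na(nodes$parent)]
  txt <- paste0(fmt(root), ";")
  if (!is.null(file)) {
    write_lines_file(txt, file)
    return(invisible(txt))
  }
  txt
}

# children in preorder, as a named list over every node id
tree_children_map <- function(tree) {
  n <- tree$nodes
  split(n$node_id[!is.na(n$parent)],
        factor(n$parent[!is.na(n$parent)], levels = n$node_id))
}

tree_root <- function(tree) tree$nodes$node_id[is.na(tree$nodes$parent)]

tree_leaf_ids <- function(tree) tree$nodes$node_id[tree$nodes$is_leaf]

# resolve a node reference that may be a node_id or a full DB:ACC gene id
resolve_node <- function(tree, id) {
  if (id %in% tree$nodes$node_id) return(id)
  hit <- match(id, tree$nodes$gene_id)
  if (!is.na(hit)) return(tree$nodes$node_id[hit])
  abort(sprintf("unknown node: %s", id), class = "phyloanno_lookup_error")
}

path_to_root <- function(tree, node_id) {
  parents <- stats::setNames(tree$nodes$parent, tree$nodes$node_id)
  path <- character()
  v <- node_id
  while (!is.na(v)) {
    path <- c(path, v)
    v <- parents[[v]]
  }
  path
}

#' Most recent common ancestor of a node set
#'
#' The deepest node that is ancestral-or-equal to every node in `ids`. The
#' MRCA of experimentally supported leaves is where the Dollo suggester
#' anchors a gain: the most recent point at which the function can have
#' evolved once and still be inherited by all supported genes.
#'
#' @param tree A `gene_tree`.
#' @param ids Nonempty character vector of node ids (leaf accessions and
#'   full `DB:ACC` gene ids are accepted).
#' @return A single node id.
#' @export
tree_mrca <- function(tree, ids) {
  stopifnot(length(ids) >= 1)
  ids <- vapply(ids, function(i) resolve_node(tree, i), character(1))
  paths <- lapply(unique(ids), function(i) path_to_root(tree, i))
  common <- Reduce(intersect, paths)  # ordered deepest-first along path 1
  common[1]
}

#' Strict descendants of a node
#'
#' @param tree A `gene_tree`.
#' @param node_id A node id (the node itself is excluded from the result).
#' @param leaves_only Return only leaf descendants?
#' @return Character vector of node ids, in preorder.
#' @export
tree_descendants <- function(tree, node_id, leaves_only = FALSE) {
  node_id <- resolve_node(tree, node_id)
  kids <- tree_children_map(tree)
  out <- descend_from(kids, node_id)
  if (leaves_only) out <- intersect(out, tree_leaf_ids(tree))
  ord <- stats::setNames(tree$nodes$preorder, tree$nodes$node_id)
  out[order(ord[out])]
}

descend_from <- function(kids, node_id) {
  seen <- character()
  frontier <- node_id
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# leaves at-or-under a node (a leaf's own leaf set is itself)
leaves_under <- function(tree, node_id, kids = NULL) {
  node_id <- resolve_node(tree, node_id)
  if (tree$nodes$is_leaf[match(node_id, tree$nodes$node_id)]) return(node_id)
  kids <- kids %||% tree_children_map(tree)
  intersect(descend_from(kids, node_id), tree_leaf_ids(tree))
}

# is `a` an ancestor-or-equal of `b`?
is_ancestor <- function(tree, a, b) {
  a <- resolve_node(tree, a)
  b <- resolve_node(tree, b)
  a %in% path_to_root(tree, b)
}

node_depths <- function(tree) {
  n <- tree$nodes
  depth <- stats::setNames(integer(nrow(n)), n$node_id)
  for (i in seq_len(nrow(n))) {  # preorder: parent precedes child
    p <- n$parent[i]
    depth[n$node_id[i]] <- if (is.na(p)) 0L else depth[[p]] + 1L
  }
  depth
}

#' Plot a gene tree
#'
#' Simple rectangular layout with node events colour-coded; optionally
#' overlays inferred annotations (IBD gain points, IBA leaf ticks, IKR/IRD
#' loss marks) produced by [propagate()].
#'
#' @param object A `gene_tree`.
#' @param inferred Optional `inferred_annotations` tibble to overlay.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_tree <- function(object, inferred = NULL, ...) {
  n <- object$nodes
  depth <- node_depths(object)
  y <- stats::setNames(rep(NA_real_, nrow(n)), n$node_id)
  leaves <- n$node_id[n$is_leaf]
  y[leaves] <- seq_along(leaves)
  for (i in rev(seq_len(nrow(n)))) {  # reverse preorder: children first
    if (!n$is_leaf[i]) {
      kids <- n$node_id[!is.na(n$parent) & n$parent == n$node_id[i]]
      y[n$node_id[i]] <- mean(y[kids])
    }
  }
  df <- tibble(node_id = n$node_id, parent = n$parent, event = n$event,
               x = as.numeric(depth[n$node_id]), y = as.numeric(y[n$node_id]),
               label = ifelse(n$is_leaf, n$gene_id, n$node_id))
  seg <- df[!is.na(df$parent), ]
  seg$xend <- df$x[match(seg$parent, df$node_id)]
  seg$yend <- df$y[match(seg$parent, df$node_id)]
  p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = seg, aes(xend = .data$xend, yend = .data$yend),
                 colour = "grey50") +
    geom_point(aes(colour = .data$event), size = 2) +
    geom_text(aes(label = .data$label), hjust = -0.15, size = 3) +
    scale_x_continuous(expand = expansion(mult = c(0.05, 0.25))) +
    labs(x = "depth", y = NULL, colour = "event") +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid = element_blank())
  if (!is.null(inferred) && nrow(inferred)) {
    ov <- inferred
    ov$x <- df$x[match(ov$target, df$node_id)]
    ov$y <- df$y[match(ov$target, df$node_id)]
    p <- p + geom_point(data = ov, aes(shape = .data$evidence),
                        size = 4, stroke = 1, colour = "black", fill = NA) +
      scale_shape_manual(values = c(IBD = 5, IBA = 1, IKR = 4, IRD = 4))
  }
  p
}
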