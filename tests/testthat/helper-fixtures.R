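# Shared fixtures, built in code.

# three-term is_a chain: t3 is_a t2 is_a t1
chain_obo_text <- function() {
  paste(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root process",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: mid process",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root process",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: leaf process",
    "namespace: biological_process",
    "is_a: GO:0000002",
    sep = "\n")
}

chain_ontology <- function() parse_obo(chain_obo_text())

# the worked 3-leaf family: ((HUM1,MUS1)AN1,DRO1)AN0
fixture_tree_text <- function() {
  paste0("((A:HUM1[&&NHX:S=HUMAN],B:MUS1[&&NHX:S=MOUSE])",
         "[&&NHX:ID=AN1:Ev=D],C:DRO1[&&NHX:S=DROME])[&&NHX:ID=AN0:Ev=S];")
}

fixture_tree <- function() parse_tree(fixture_tree_text(), "PTHRTEST")

# independent random-DAG OBO emitter (does not go through write_obo or
# simulate_ontology): term i gets 1-2 parents among terms 1..i-1
random_dag_obo <- function(n_terms, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    lines <- c("format-version: 1.2")
    edges <- list()
    for (i in seq_len(n_terms)) {
      stanza <- c("", "[Term]", paste0("id: ", ids[i]),
                  paste0("name: term ", i),
                  "namespace: biological_process")
      if (i > 1) {
        np <- sample(1:2, 1)
        parents <- sample(seq_len(i - 1), min(np, i - 1))
        for (p in parents) {
          if (stats::runif(1) < 0.75) {
            stanza <- c(stanza, paste0("is_a: ", ids[p]))
            edges[[length(edges) + 1L]] <- c(ids[i], ids[p], "is_a")
          } else {
            stanza <- c(stanza, paste0("relationship: part_of ", ids[p]))
            edges[[length(edges) + 1L]] <- c(ids[i], ids[p], "part_of")
          }
        }
      }
      lines <- c(lines, stanza)
    }
    list(text = paste(lines, collapse = "\n"), ids = ids,
         edges = do.call(rbind, edges))
  })
}

# a random model with up to max_gains gains (distinct terms) and up to
# max_losses losses on a simulated family; structurally valid by
# construction
random_model <- function(fam, seed, max_gains = 5, max_losses = 5) {
  tree <- fam$tree
  ontology <- fam$ontology
  withr::with_seed(seed, {
    internals <- tree$nodes$node_id[!tree$nodes$is_leaf]
    terms <- ontology$terms$id
    n_gains <- sample.int(min(max_gains, length(terms)), 1)
    gain_terms <- sample(terms, n_gains)
    gains <- lapply(seq_len(n_gains), function(i) {
      node <- sample(internals, 1)
      lv <- tree_descendants(tree, node, leaves_only = TRUE)
      tibble::tibble(node_id = node, go_id = gain_terms[i],
                     supporting_leaves = list(sort(sample(lv, min(2, length(lv))))),
                     references = list(character()))
    })
    gains <- dplyr::bind_rows(gains)
    losses <- list()
    n_losses <- sample.int(max_losses + 1, 1) - 1L
    for (k in seq_len(n_losses)) {
      gi <- sample.int(nrow(gains), 1)
      below <- tree_descendants(tree, gains$node_id[gi])
      if (length(below) == 0) next
      node <- sample(below, 1)
      anc <- go_ancestors(ontology, gains$go_id[gi], reflexive = TRUE)
      losses[[length(losses) + 1L]] <- tibble::tibble(
        node_id = node, go_id = sample(anc, 1), cause = "UNSPECIFIED")
    }
    losses <- if (length(losses)) dplyr::bind_rows(losses) else NULL
    evolutionary_model(tree$family_id, gains, losses)
  })
}
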