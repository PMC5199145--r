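#' Simulation parameters for synthetic families
#'
#' Defines the generating conditions for a synthetic gene family with known
#' ground truth: a random binary gene tree, a small random GO-like DAG, a
#' single true gain of the target function, per-edge losses below it, and
#' an annotation layer with imperfect observation and noise. Defaults model
#' a mid-sized, moderately studied family: 64 extant genes; 20% of internal
#' nodes are duplications (reconciled vertebrate family trees are
#' duplication-rich); a function, once gained, is lost on 10% of descendant
#' edges; 60% of truly functional genes have been experimentally
#' characterized (most genes in most families have no direct experimental
#' GO evidence); a 1% spurious-annotation rate, matching the
#' false-discovery rate conventionally accepted in high-throughput
#' publication; and a 10% chance that a truly non-functional gene below the
#' gain has been explicitly shown *not* to carry the function (negative
#' results are rarely published).
#'
#' @param n_leaves Number of extant genes (>= 2).
#' @param p_duplication Probability an internal node is a duplication.
#' @param p_loss Per-edge probability of losing the function below the
#'   gain.
#' @param p_observe Probability a functional leaf carries a usable
#'   experimental record.
#' @param p_false_positive Probability a non-functional leaf carries a
#'   spurious experimental record.
#' @param p_negative Probability a non-functional leaf below the gain
#'   carries a NOT record.
#' @param n_terms Ontology size (>= 3, so the target term can have an
#'   ancestor and a descendant).
#' @param seed Integer seed; all generation stages derive named substreams
#'   from it, so results are bit-identical under a fixed seed and adding
#'   stages never perturbs earlier draws.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_leaves = 64, p_duplication = 0.2, p_loss = 0.1,
                       p_observe = 0.6, p_false_positive = 0.01,
                       p_negative = 0.1, n_terms = 20, seed = 1) {
  probs <- c(p_duplication = p_duplication, p_loss = p_loss,
             p_observe = p_observe, p_false_positive = p_false_positive,
             p_negative = p_negative)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", class = "phyloanno_config_error")
  }
  if (n_leaves < 2) abort("n_leaves must be >= 2", class = "phyloanno_config_error")
  if (n_terms < 3) abort("n_terms must be >= 3", class = "phyloanno_config_error")
  structure(list(n_leaves = as.integer(n_leaves),
                 p_duplication = p_duplication, p_loss = p_loss,
                 p_observe = p_observe, p_false_positive = p_false_positive,
                 p_negative = p_negative, n_terms = as.integer(n_terms),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Stage indices into the per-seed substream table. Annotation stages live
# after the family stages so the two generators can be called independently.
SIM_STAGES <- c(topology = 1L, events = 2L, species = 3L, ontology = 4L,
                gain = 5L, losses = 6L, observe = 7L, false_positive = 8L,
                negative = 9L)

sim_stage_seed <- function(params, stage) {
  derive_seeds(params$seed, max(SIM_STAGES))[SIM_STAGES[[stage]]]
}

#' Simulate a gene family with known gain/loss ground truth
#'
#' Generates a random rooted binary gene tree (sequential leaf attachment:
#' each new leaf splits a uniformly chosen existing leaf), assigns
#' duplication/speciation events and species codes, builds a small random
#' ontology DAG whose target term has at least one ancestor and one
#' descendant, draws the true gain node uniformly among internal nodes with
#' at least two leaf descendants, and drops the function on each edge below
#' the gain independently with `p_loss` (nested losses are pruned to the
#' maximal ones). The gene tree is generated directly rather than by
#' species-tree reconciliation: that is adequate for exercising the
#' inference machinery, whose input contract is just a rooted event-labelled
#' tree.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_family` with elements `tree` (a
#'   `gene_tree`), `ontology` (an `ontology_graph`) and `truth` (class
#'   `sim_truth`: `gain_node`, `loss_nodes`, `functional_leaves`, `term`).
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_leaves

  # --- topology: integer parent/children arrays, leaves attached one by one
  topo <- withr::with_seed(sim_stage_seed(params, "topology"), {
    parent <- c(NA_integer_, 1L, 1L)
    is_leaf <- c(FALSE, TRUE, TRUE)
    kids <- list(c(2L, 3L), integer(), integer())
    k <- 2L
    while (k < n) {
      leaves <- which(is_leaf)
      x <- leaves[sample.int(length(leaves), 1)]
      newint <- length(parent) + 1L
      newleaf <- length(parent) + 2L
      p <- parent[x]
      kids[[p]][kids[[p]] == x] <- newint
      parent[newint] <- p
      parent[newleaf] <- newint
      parent[x] <- newint
      is_leaf[newint] <- FALSE
      is_leaf[newleaf] <- TRUE
      kids[[newint]] <- c(x, newleaf)
      kids[[newleaf]] <- integer()
      k <- k + 1L
    }
    list(parent = parent, is_leaf = is_leaf, kids = kids)
  })

  # preorder walk
  n_nodes <- length(topo$parent)
  pre <- integer(0)
  stack <- 1L
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    pre <- c(pre, v)
    stack <- c(topo$kids[[v]], stack)
  }
  pre_rank <- match(seq_len(n_nodes), pre)

  internals <- which(!topo$is_leaf)
  leaves <- which(topo$is_leaf)
  events <- withr::with_seed(sim_stage_seed(params, "events"), {
    ifelse(stats::runif(length(internals)) < params$p_duplication,
           "duplication", "speciation")
  })
  species_pool <- c("HUMAN", "MOUSE", "RAT", "DROME", "YEAST", "ARATH",
                    "CAEEL", "DANRE")
  leaf_species <- withr::with_seed(sim_stage_seed(params, "species"), {
    sample(species_pool, length(leaves), replace = TRUE)
  })

  node_id <- character(n_nodes)
  node_id[internals] <- sprintf("AN%d", rank(pre_rank[internals]) - 1L)
  node_id[leaves] <- sprintf("G%04d", rank(pre_rank[leaves]))
  gene_id <- ifelse(topo$is_leaf, paste0("GN:", node_id), NA_character_)
  species <- rep(NA_character_, n_nodes)
  species[leaves] <- leaf_species
  event <- rep("leaf", n_nodes)
  event[internals] <- events
  # branch lengths are cosmetic (inference is event-based); snap them to the
  # writer's 6-decimal grid so serialization round-trips bit-exactly
  blen <- withr::with_seed(sim_stage_seed(params, "topology") + 1L,
                           as.numeric(sprintf("%.6f",
                                              stats::runif(n_nodes, 0.01, 1))))
  blen[1] <- NA_real_

  parent_id <- ifelse(is.na(topo$parent), NA_character_,
                      node_id[topo$parent])
  nodes <- tibble(
    node_id = node_id[pre],
    parent = parent_id[pre],
    event = event[pre], species = species[pre], gene_id = gene_id[pre],
    branch_length = blen[pre], is_leaf = topo$is_leaf[pre],
    preorder = seq_len(n_nodes) - 1L
  )
  fam_seed_tag <- sprintf("SIM%05d", params$seed %% 100000L)
  tree <- new_gene_tree(fam_seed_tag, nodes)

  ontology <- simulate_ontology(params)
  target <- sim_target_term(params)

  kids_map <- tree_children_map(tree)
  eligible <- vapply(tree$nodes$node_id[!tree$nodes$is_leaf], function(v) {
    length(leaves_under(tree, v, kids_map)) >= 2
  }, logical(1))
  eligible_nodes <- tree$nodes$node_id[!tree$nodes$is_leaf][eligible]
  if (length(eligible_nodes) == 0) {
    abort("no internal node with >= 2 leaf descendants",
          class = "phyloanno_generation_error")
  }
  gain_node <- withr::with_seed(sim_stage_seed(params, "gain"), {
    eligible_nodes[sample.int(length(eligible_nodes), 1)]
  })

  below <- tree_descendants(tree, gain_node)
  lost <- withr::with_seed(sim_stage_seed(params, "losses"), {
    below[stats::runif(length(below)) < params$p_loss]
  })
  # prune to maximal loss nodes (an edge under an already-lost edge is moot)
  if (length(lost) > 1) {
    keep <- vapply(lost, function(v) {
      !any(vapply(setdiff(lost, v), function(w) is_ancestor(tree, w, v),
                  logical(1)))
    }, logical(1))
    lost <- lost[keep]
  }
  gain_leaves <- leaves_under(tree, gain_node, kids_map)
  lost_leaves <- unique(unlist(lapply(lost, function(v)
    leaves_under(tree, v, kids_map)), use.names = FALSE))
  truth <- structure(
    list(gain_node = gain_node, loss_nodes = sort(lost),
         functional_leaves = sort(setdiff(gain_leaves, lost_leaves)),
         term = target),
    class = "sim_truth")
  structure(list(tree = tree, ontology = ontology, truth = truth),
            class = "sim_family")
}

sim_target_term <- function(params) {
  sprintf("GO:%07d", ceiling(params$n_terms / 2))
}

simulate_ontology <- function(params) {
  nt <- params$n_terms
  ids <- sprintf("GO:%07d", seq_len(nt))
  target_i <- ceiling(nt / 2)
  withr::with_seed(sim_stage_seed(params, "ontology"), {
    edges <- list()
    for (i in 2:nt) {
      np <- 1L + stats::rbinom(1, 1, 0.3)
      parents <- sample.int(i - 1L, min(np, i - 1L))
      # the term after the target always descends from it, so the target
      # term has at least one descendant
      if (i == target_i + 1L && !(target_i %in% parents)) {
        parents[1] <- target_i
      }
      rel <- ifelse(stats::runif(length(parents)) < 0.8, "is_a", "part_of")
      edges[[i]] <- tibble(child = ids[i], parent = ids[parents],
                           relation = rel)
    }
    terms <- tibble(id = ids, name = paste("synthetic term", seq_len(nt)),
                    namespace = "biological_process", obsolete = FALSE,
                    replaced_by = NA_character_)
    new_ontology_graph(terms, distinct(bind_rows(edges)))
  })
}

#' Simulate an experimental annotation layer over a family
#'
#' Functional leaves are observed with probability `p_observe` and receive
#' an IDA record to the true term or (half the time, when one exists) a
#' random ontology descendant of it — mirroring real corpora, where
#' evidence is often recorded at a more specific term than the one being
#' propagated. Non-functional leaves receive spurious IMP records with
#' probability `p_false_positive` (mutant-phenotype evidence is the
#' archetypal source of indirect-effect noise), and non-functional leaves
#' below the gain receive NOT-IMP records with probability `p_negative`.
#' Leaves are visited in preorder, one draw per leaf per stage, so output
#' is bit-identical under a fixed seed.
#'
#' @param tree,ontology,truth Output of [simulate_family()].
#' @param params The same [sim_params()].
#' @return A GAF record tibble.
#' @export
simulate_annotations <- function(tree, ontology, truth, params) {
  leaves <- tree_leaf_ids(tree)
  functional <- truth$functional_leaves
  nonfunctional <- setdiff(leaves, functional)
  below_gain <- tree_descendants(tree, truth$gain_node, leaves_only = TRUE)
  species <- stats::setNames(tree$nodes$species, tree$nodes$node_id)
  recs <- list()

  desc_terms <- go_descendants(ontology, truth$term)
  obs <- withr::with_seed(sim_stage_seed(params, "observe"), {
    draw <- stats::runif(length(functional)) < params$p_observe
    pick_desc <- stats::runif(length(functional)) < 0.5
    which_desc <- if (length(desc_terms)) {
      sample(desc_terms, length(functional), replace = TRUE)
    } else rep(truth$term, length(functional))
    list(draw = draw, term = ifelse(pick_desc & length(desc_terms) > 0,
                                    which_desc, truth$term))
  })
  if (any(obs$draw)) {
    idx <- which(obs$draw)
    recs[[length(recs) + 1L]] <- gaf_record(
      db = "GN", object_id = functional[idx], go_id = obs$term[idx],
      evidence_code = "IDA",
      references = as.list(sprintf("PMID:%07d", 100000L + idx)),
      taxon = paste0("taxon:", species[functional[idx]]),
      assigned_by = "sim")
  }

  fp <- withr::with_seed(sim_stage_seed(params, "false_positive"), {
    stats::runif(length(nonfunctional)) < params$p_false_positive
  })
  if (any(fp)) {
    idx <- which(fp)
    recs[[length(recs) + 1L]] <- gaf_record(
      db = "GN", object_id = nonfunctional[idx], go_id = truth$term,
      evidence_code = "IMP",
      references = as.list(sprintf("PMID:%07d", 200000L + idx)),
      taxon = paste0("taxon:", species[nonfunctional[idx]]),
      assigned_by = "sim")
  }

  nf_below <- intersect(nonfunctional, below_gain)
  ng <- withr::with_seed(sim_stage_seed(params, "negative"), {
    stats::runif(length(nf_below)) < params$p_negative
  })
  if (any(ng)) {
    idx <- which(ng)
    recs[[length(recs) + 1L]] <- gaf_record(
      db = "GN", object_id = nf_below[idx], go_id = truth$term,
      evidence_code = "IMP", qualifier = "NOT",
      references = as.list(sprintf("PMID:%07d", 300000L + idx)),
      taxon = paste0("taxon:", species[nf_below[idx]]),
      assigned_by = "sim")
  }
  if (length(recs)) bind_rows(recs) else empty_gaf()
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_truth <- function(truth, file) {
  write_json_report(unclass(truth), file)
}

#' Gain-recovery experiment on synthetic families
#'
#' The end-to-end harness for the Dollo suggester: simulate a family and
#' its annotation layer, derive presence/negation sets for the true term,
#' run [suggest_model()], and compare the suggestion with the simulated
#' truth. Reports the exact gain-node match rate (replicates with no
#' usable evidence count as misses), the mean Jaccard similarity between
#' suggested and true loss sets (over replicates with evidence; two empty
#' sets have Jaccard 1), and the number of no-evidence replicates.
#' Replicate seeds are derived from `params$seed`, so the experiment is
#' deterministic.
#'
#' @param params A [sim_params()].
#' @param n_reps Number of replicates (>= 1).
#' @return A one-row tibble of class `recovery_summary`: `n_reps`,
#'   `n_no_evidence`, `match_rate`, `mean_loss_jaccard`.
#' @export
recovery_experiment <- function(params, n_reps) {
  stopifnot(n_reps >= 1)
  rep_seeds <- derive_seeds(params$seed, max(SIM_STAGES) + n_reps)[-seq_len(max(SIM_STAGES))]
  match <- logical(n_reps)
  jac <- rep(NA_real_, n_reps)
  no_evidence <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- rep_seeds[r]
    fam <- simulate_family(p)
    recs <- simulate_annotations(fam$tree, fam$ontology, fam$truth, p)
    ps <- if (nrow(recs)) {
      suppressWarnings(
        presence_sets(fam$tree, recs, fam$ontology, fam$truth$term))
    } else list(P = character(), N = character())
    if (length(ps$P) == 0) {
      no_evidence[r] <- TRUE
      next
    }
    sug <- suggest_model(fam$tree, ps$P, ps$N, fam$truth$term)
    match[r] <- identical(sug$model$gains$node_id[1], fam$truth$gain_node)
    jac[r] <- jaccard(sug$model$losses$node_id, fam$truth$loss_nodes)
  }
  out <- tibble(n_reps = as.integer(n_reps),
                n_no_evidence = sum(no_evidence),
                match_rate = mean(match),
                mean_loss_jaccard = if (all(no_evidence)) NA_real_
                                    else mean(jac, na.rm = TRUE))
  class(out) <- c("recovery_summary", class(out))
  out
}

#' Recovery as a function of observation probability
#'
#' Runs [recovery_experiment()] over a grid of `p_observe` values with
#' common random numbers (the same replicate families at every grid
#' point), isolating the effect of observation coverage on gain recovery.
#'
#' @param params Baseline [sim_params()].
#' @param p_observe Vector of observation probabilities.
#' @param n_reps Replicates per grid point.
#' @return A tibble of class `recovery_grid`: one row per grid point with
#'   the [recovery_experiment()] columns plus `p_observe`.
#' @export
recovery_grid <- function(params, p_observe = c(1, 0.8, 0.6, 0.4),
                          n_reps = 200) {
  rows <- lapply(p_observe, function(p) {
    pp <- params
    pp$p_observe <- p
    cbind(tibble(p_observe = p), recovery_experiment(pp, n_reps))
  })
  out <- as_tibble(do.call(rbind, rows))
  class(out) <- c("recovery_grid", class(out))
  out
}

#' Plot a recovery grid
#'
#' @param object A `recovery_grid`.
#' @param ... Ignored.
#' @return A ggplot of gain match rate against observation probability.
#' @exportS3Method ggplot2::autoplot
autoplot.recovery_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$p_observe, y = .data$match_rate)) +
    geom_line() +
    geom_point(size = 2) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "observation probability per functional gene",
         y = "exact gain-node match rate") +
    theme_minimal()
}
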