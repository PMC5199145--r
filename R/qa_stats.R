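#' Family-level annotation statistics
#'
#' Computes the standard per-family summary of a phylogenetic annotation
#' run: how many proteins the family contains, how many carry experimental
#' evidence, how many experimental records and distinct terms feed the
#' inference, and how many IBD/IBA annotations and distinct inferred terms
#' the model produced. Counts follow the usual reporting conventions:
#' experimental columns count annotation *records* (not gene-term pairs);
#' `annotated_proteins` counts distinct extant proteins with at least one
#' IBA; ancestral IBD rows are counted separately and never as protein
#' annotations. `inferred_terms` may legitimately differ from `exp_terms`,
#' since inference may use a more general or more specific term than the
#' evidence.
#'
#' @param tree A `gene_tree`.
#' @param usable_records Usable experimental records (see
#'   [filter_experimental()]). Records referencing genes absent from the
#'   tree are excluded from the counts and reported via a warning and the
#'   `"excluded_records"` attribute.
#' @param inferred Output of [propagate()] (may be zero rows).
#' @return A one-row tibble of class `family_stats` with columns
#'   `family_id`, `protein_count`, `exp_proteins`, `exp_annotations`,
#'   `exp_terms`, `annotated_proteins`, `ibd_count`, `iba_count`,
#'   `inferred_terms`.
#' @export
family_stats <- function(tree, usable_records, inferred) {
  leaves <- tree_leaf_ids(tree)
  unknown <- usable_records[!(usable_records$object_id %in% leaves), ,
                            drop = FALSE]
  if (nrow(unknown)) {
    warn(sprintf("%d record(s) reference genes absent from the tree; excluded",
                 nrow(unknown)))
  }
  rec <- usable_records[usable_records$object_id %in% leaves, , drop = FALSE]
  out <- tibble(
    family_id = tree$family_id,
    protein_count = length(leaves),
    exp_proteins = n_distinct(rec$object_id),
    exp_annotations = nrow(rec),
    exp_terms = n_distinct(rec$go_id),
    annotated_proteins = n_distinct(
      inferred$target[inferred$evidence == "IBA" & inferred$is_leaf]),
    ibd_count = sum(inferred$evidence == "IBD"),
    iba_count = sum(inferred$evidence == "IBA"),
    inferred_terms = n_distinct(inferred$go_id[inferred$evidence == "IBD"])
  )
  attr(out, "excluded_records") <- unknown
  class(out) <- c("family_stats", class(out))
  out
}

#' Write family statistics as TSV
#'
#' Fixed nine-column header in the canonical order; one row per family.
#'
#' @param stats One or more `family_stats` rows (bind rows for several
#'   families).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_family_stats <- function(stats, file) {
  cols <- c("family_id", "protein_count", "exp_proteins", "exp_annotations",
            "exp_terms", "annotated_proteins", "ibd_count", "iba_count",
            "inferred_terms")
  write_tsv_report(as_tibble(stats)[, cols], file)
}

#' Newly inferred gene-function assignments
#'
#' The genuinely new knowledge produced by propagation: IBA annotations on
#' extant genes that lack any usable experimental record to the same term
#' or an ontology descendant of it. An IBA to a general term on a leaf
#' whose experimental evidence is more specific is *not* new (the
#' true-path rule already implies it); an IBA to a term more specific than
#' the leaf's experimental evidence *is* new.
#'
#' @param inferred Output of [propagate()].
#' @param usable_records Usable experimental records.
#' @param ontology An `ontology_graph`.
#' @param species_filter Optional species code; restricts the result to
#'   leaves of that species.
#' @return Tibble with columns `gene`, `go_id`, `species`.
#' @export
new_annotations <- function(inferred, usable_records, ontology,
                            species_filter = NULL) {
  iba <- inferred[inferred$evidence == "IBA" & inferred$is_leaf, , drop = FALSE]
  iba <- distinct(tibble(gene = iba$target, go_id = iba$go_id,
                         species = iba$species))
  if (!is.null(species_filter)) {
    iba <- iba[!is.na(iba$species) & iba$species %in% species_filter, ,
               drop = FALSE]
  }
  if (nrow(iba) == 0) return(iba)
  is_new <- vapply(seq_len(nrow(iba)), function(i) {
    dsc <- go_descendants(ontology, iba$go_id[i], reflexive = TRUE)
    !any(usable_records$object_id == iba$gene[i] &
           usable_records$go_id %in% dsc)
  }, logical(1))
  iba[is_new, , drop = FALSE]
}

#' Over-annotation QA configuration
#'
#' The phenotype-prone and transient-localization term lists are curator
#' policy, not algorithm — the shipped defaults are empty and projects
#' supply their own (e.g. phenotype-level process terms that mutant screens
#' over-assign, or compartments a protein only transits during
#' biosynthesis).
#'
#' @param phenotype_prone_terms GO ids of process terms frequently
#'   over-annotated from mutant phenotypes.
#' @param transient_localization_terms GO ids of cellular components that
#'   reflect transient residence rather than the site of function.
#' @param evidence An [evidence_config()].
#' @return An object of class `qa_config`.
#' @export
qa_config <- function(phenotype_prone_terms = character(),
                      transient_localization_terms = character(),
                      evidence = evidence_config()) {
  structure(list(phenotype_prone_terms = phenotype_prone_terms,
                 transient_localization_terms = transient_localization_terms,
                 evidence = evidence),
            class = "qa_config")
}

#' Flag annotations prone to over-annotation
#'
#' Screens primary annotations for the classic sources of false positives
#' in GO: high-throughput evidence (high false-positive rates, especially
#' for localization); mutant-phenotype evidence (IMP/IGI) attached to
#' listed phenotype-prone process terms (a phenotype shows an indirect
#' effect, not necessarily a direct role); cellular-component annotations
#' to listed transient compartments; and aspect/namespace mismatches.
#' One flag is emitted per (record, rule) hit.
#'
#' @param records GAF records.
#' @param ontology Optional `ontology_graph`; enables the aspect-mismatch
#'   rule.
#' @param config A [qa_config()].
#' @return Tibble with columns `db`, `object_id`, `go_id`,
#'   `evidence_code`, `rule`, `note`.
#' @export
flag_overannotation <- function(records, ontology = NULL,
                                config = qa_config()) {
  flags <- list()
  add <- function(idx, rule, note) {
    if (!any(idx)) return(invisible(NULL))
    flags[[length(flags) + 1L]] <<- tibble(
      db = records$db[idx], object_id = records$object_id[idx],
      go_id = records$go_id[idx], evidence_code = records$evidence_code[idx],
      rule = rule, note = note)
  }
  add(records$evidence_code %in% config$evidence$htp_codes, "htp_evidence",
      "high-throughput evidence; high false-positive rate")
  add(records$go_id %in% config$phenotype_prone_terms &
        records$evidence_code %in% c("IMP", "IGI"),
      "phenotype_prone_term",
      "mutant-phenotype evidence on a phenotype-prone term")
  add(records$aspect == "C" &
        records$go_id %in% config$transient_localization_terms,
      "transient_localization",
      "component reflects transient residence, not site of function")
  if (!is.null(ontology)) {
    ns_letter <- c(molecular_function = "F", biological_process = "P",
                   cellular_component = "C")
    ns <- ontology$terms$namespace[match(records$go_id, ontology$terms$id)]
    add(!is.na(ns) & !is.na(ns_letter[ns]) &
          records$aspect != unname(ns_letter[ns]),
        "aspect_mismatch", "GAF aspect disagrees with term namespace")
  }
  if (length(flags)) bind_rows(flags) else
    tibble(db = character(), object_id = character(), go_id = character(),
           evidence_code = character(), rule = character(), note = character())
}

#' Re-check a model against updated inputs
#'
#' The inputs behind a phylogenetic annotation move under it: GO terms are
#' obsoleted or merged, primary annotations are withdrawn, trees are
#' rebuilt and sequences move between families. This check re-validates
#' every gain of a previously valid model against new versions of the
#' tree, ontology and annotation set, and reports what broke together with
#' suggested fixes.
#'
#' Reasons reported per gain: `term_obsoleted` (term gone, or obsolete with
#' no replacement), `term_merged` (obsolete with a `replaced_by` pointer —
#' the action proposes the rewrite), `leaf_missing_from_tree` /
#' `leaf_moved_family` (a supporting sequence left the tree; the latter
#' when a cross-family index locates it elsewhere), and
#' `support_record_removed` (a supporting leaf no longer carries a usable
#' record to the term or an ontology descendant; when no support survives
#' at all, the action escalates to retracting the gain).
#'
#' @param model A previously valid `evolutionary_model`.
#' @param new_tree,new_ontology,new_records The updated inputs.
#' @param config An [evidence_config()].
#' @param cross_family_index Optional named character vector mapping leaf
#'   ids to the family that now contains them.
#' @return A tibble of class `maintenance_report` with columns
#'   `gain_node`, `go_id`, `reason`, `detail`, `action`; zero rows when
#'   nothing broke.
#' @export
maintenance_check <- function(model, new_tree, new_ontology, new_records,
                              config = evidence_config(),
                              cross_family_index = NULL) {
  usable <- filter_experimental(new_records, config)$usable
  tree_nodes <- c(new_tree$nodes$node_id, new_tree$nodes$gene_id)
  out <- list()
  add <- function(gain_node, go_id, reason, detail, action = NA_character_) {
    out[[length(out) + 1L]] <<- tibble(gain_node = gain_node, go_id = go_id,
                                       reason = reason, detail = detail,
                                       action = action)
  }
  g <- model$gains
  for (i in seq_len(nrow(g))) {
    term <- g$go_id[i]
    effective <- term
    if (!(term %in% new_ontology$terms$id)) {
      add(g$node_id[i], term, "term_obsoleted",
          "term absent from updated ontology")
      effective <- NA_character_
    } else {
      row <- match(term, new_ontology$terms$id)
      if (new_ontology$terms$obsolete[row]) {
        rep <- new_ontology$terms$replaced_by[row]
        if (is.na(rep) || !nzchar(rep)) {
          add(g$node_id[i], term, "term_obsoleted",
              "term obsoleted with no replacement")
          effective <- NA_character_
        } else {
          add(g$node_id[i], term, "term_merged",
              sprintf("term obsoleted, replaced by %s", rep),
              sprintf("rewrite %s -> %s", term, rep))
          effective <- rep
        }
      }
    }
    leaves <- g$supporting_leaves[[i]]
    present <- leaves[leaves %in% tree_nodes]
    for (leaf in setdiff(leaves, present)) {
      if (!is.null(cross_family_index) && leaf %in% names(cross_family_index)) {
        add(g$node_id[i], term, "leaf_moved_family",
            sprintf("support leaf %s now in family %s", leaf,
                    cross_family_index[[leaf]]),
            sprintf("move support for %s to family %s", leaf,
                    cross_family_index[[leaf]]))
      } else {
        add(g$node_id[i], term, "leaf_missing_from_tree",
            sprintf("support leaf %s absent from updated tree", leaf))
      }
    }
    if (!is.na(effective)) {
      ok_terms <- go_descendants(new_ontology, effective, reflexive = TRUE)
      has_record <- vapply(present, function(leaf) {
        acc <- tryCatch(resolve_node(new_tree, leaf), error = function(e) leaf)
        any(usable$object_id == acc & usable$go_id %in% ok_terms)
      }, logical(1))
      none_left <- !any(has_record)
      for (leaf in present[!has_record]) {
        add(g$node_id[i], term, "support_record_removed",
            sprintf("support leaf %s no longer carries a usable record to %s or a descendant",
                    leaf, effective),
            if (none_left) "re-curate or retract the gain"
            else "drop the leaf from the gain's support")
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(gain_node = character(), go_id = character(), reason = character(),
           detail = character(), action = character())
  class(res) <- c("maintenance_report", class(res))
  res
}

#' @exportS3Method generics::tidy
tidy.maintenance_report <- function(x, ...) as_tibble(unclass(x))
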