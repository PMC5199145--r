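test_that("family statistics match hand-enumerated fixtures", {
  tr <- fixture_tree()
  g <- chain_ontology()

  empty <- family_stats(tr, empty_gaf(),
                        propagate(evolutionary_model("PTHRTEST"), tr, g))
  expect_equal(empty$protein_count, 3)
  expect_equal(unlist(empty[, c("exp_proteins", "exp_annotations", "exp_terms",
                                "annotated_proteins", "ibd_count", "iba_count",
                                "inferred_terms")]),
               c(exp_proteins = 0, exp_annotations = 0, exp_terms = 0,
                 annotated_proteins = 0, ibd_count = 0, iba_count = 0,
                 inferred_terms = 0))

  # one leaf with two IDA records to two terms; gain at AN1
  recs <- gaf_record(db = "A", object_id = "HUM1",
                     go_id = c("GO:0000002", "GO:0000003"),
                     evidence_code = "IDA")
  m <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000003", supporting_leaves = list("HUM1")))
  fs <- family_stats(tr, recs, propagate(m, tr, g, records = recs))
  expect_equal(fs$exp_proteins, 1)
  expect_equal(fs$exp_annotations, 2)
  expect_equal(fs$exp_terms, 2)
  expect_equal(fs$annotated_proteins, 2)
  expect_equal(fs$ibd_count, 1)
  expect_equal(fs$iba_count, 2)
  expect_equal(fs$inferred_terms, 1)
})

test_that("records for unknown genes are excluded and reported", {
  tr <- fixture_tree()
  g <- chain_ontology()
  recs <- gaf_record(db = "A", object_id = c("HUM1", "GHOST"),
                     go_id = "GO:0000003", evidence_code = "IDA")
  expect_warning(
    fs <- family_stats(tr, recs, propagate(evolutionary_model("PTHRTEST"),
                                           tr, g)),
    regexp = "absent")
  expect_equal(fs$exp_proteins, 1)
  expect_equal(nrow(attr(fs, "excluded_records")), 1)
})

test_that("family statistics equal a brute-force recount on synthetic families", {
  for (seed in c(14, 52, 77)) {
    p <- sim_params(n_leaves = 64, seed = seed)
    fam <- simulate_family(p)
    rec <- simulate_annotations(fam$tree, fam$ontology, fam$truth, p)
    usable <- filter_experimental(rec)$usable
    model <- random_model(fam, seed, max_gains = 3, max_losses = 3)
    inf <- propagate(model, fam$tree, fam$ontology)
    fs <- suppressWarnings(family_stats(fam$tree, usable, inf))
    want <- oracle_family_stats(fam$tree, usable, inf)
    for (col in names(want)) expect_equal(fs[[col]], want[[col]])
  }
})

test_that("new annotations are IBA without same-or-more-specific experimental support", {
  tr <- fixture_tree()
  g <- chain_ontology()
  m <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000002", supporting_leaves = list("HUM1")))
  # IBA to the parent term; HUM1 has IDA at the child term -> not new
  recs <- gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000003",
                     evidence_code = "IDA")
  inf <- propagate(m, tr, g, records = recs)
  na <- new_annotations(inf, recs, g)
  expect_equal(na$gene, "MUS1")

  # IBA to the child term; support only at the parent term -> new
  m2 <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000003", supporting_leaves = list("HUM1")))
  recs2 <- gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000002",
                      evidence_code = "IDA")
  inf2 <- propagate(m2, tr, g)
  na2 <- new_annotations(inf2, recs2, g)
  expect_setequal(na2$gene, c("HUM1", "MUS1"))

  # species filter restricts the report
  expect_equal(new_annotations(inf2, recs2, g, species_filter = "MOUSE")$gene,
               "MUS1")
})

test_that("new annotations equal the brute-force set difference on synthetic families", {
  for (seed in c(19, 63)) {
    p <- sim_params(n_leaves = 48, seed = seed)
    fam <- simulate_family(p)
    rec <- simulate_annotations(fam$tree, fam$ontology, fam$truth, p)
    usable <- filter_experimental(rec)$usable
    model <- random_model(fam, seed, max_gains = 3, max_losses = 2)
    inf <- propagate(model, fam$tree, fam$ontology)
    na <- new_annotations(inf, usable, fam$ontology)
    got <- sort(unique(paste(na$gene, na$go_id, sep = "\r")))
    expect_equal(got, oracle_new_annotations(inf, usable, fam$ontology))
    # subset of IBA leaf annotations
    iba_pairs <- paste(inf$target[inf$evidence == "IBA" & inf$is_leaf],
                       inf$go_id[inf$evidence == "IBA" & inf$is_leaf],
                       sep = "\r")
    expect_true(all(got %in% iba_pairs))
  }
})

test_that("over-annotation flags fire per rule and stay silent otherwise", {
  g <- chain_ontology()
  cfg <- qa_config(phenotype_prone_terms = "GO:0000002",
                   transient_localization_terms = "GO:0000001")
  recs <- dplyr::bind_rows(
    gaf_record(db = "GN", object_id = "A", go_id = "GO:0000001",
               evidence_code = "HDA", aspect = "P"),
    gaf_record(db = "GN", object_id = "B", go_id = "GO:0000002",
               evidence_code = "IMP", aspect = "P"),
    gaf_record(db = "GN", object_id = "C", go_id = "GO:0000001",
               evidence_code = "IDA", aspect = "C"),
    gaf_record(db = "GN", object_id = "D", go_id = "GO:0000003",
               evidence_code = "IDA", aspect = "F"))
  flags <- flag_overannotation(recs, g, cfg)
  by_rule <- split(flags$object_id, flags$rule)
  expect_equal(by_rule$htp_evidence, "A")
  expect_equal(by_rule$phenotype_prone_term, "B")
  expect_equal(by_rule$transient_localization, "C")
  # C is a BP term annotated with aspect C, D a BP term with aspect F
  expect_setequal(by_rule$aspect_mismatch, c("C", "D"))
  # clean records with empty policy lists produce no flags
  clean <- gaf_record(db = "GN", object_id = "E", go_id = "GO:0000003",
                      evidence_code = "IDA", aspect = "P")
  expect_equal(nrow(flag_overannotation(clean, g, qa_config())), 0)
})

test_that("maintenance is empty on unchanged inputs and detects each delta", {
  p <- sim_params(n_leaves = 24, p_loss = 0, p_observe = 1,
                  p_false_positive = 0, seed = 33)
  fam <- simulate_family(p)
  rec <- simulate_annotations(fam$tree, fam$ontology, fam$truth, p)
  model <- evolutionary_model(fam$tree$family_id, gains = tibble::tibble(
    node_id = fam$truth$gain_node, go_id = fam$truth$term,
    supporting_leaves = list(fam$truth$functional_leaves)))

  expect_equal(nrow(maintenance_check(model, fam$tree, fam$ontology, rec)), 0)

  # delta 1: a supporting record removed entirely
  gone <- rec[!(rec$object_id %in% fam$truth$functional_leaves), , drop = FALSE]
  r1 <- maintenance_check(model, fam$tree, fam$ontology, gone)
  expect_true("support_record_removed" %in% r1$reason)

  # delta 2: term obsoleted without replacement
  ont2 <- fam$ontology
  ont2$terms$obsolete[ont2$terms$id == fam$truth$term] <- TRUE
  ont2 <- phyloanno:::new_ontology_graph(
    ont2$terms, ont2$edges[ont2$edges$child != fam$truth$term, ])
  r2 <- maintenance_check(model, fam$tree, ont2, rec)
  expect_true("term_obsoleted" %in% r2$reason)

  # delta 3: term merged into a replacement
  ont3 <- fam$ontology
  i <- match(fam$truth$term, ont3$terms$id)
  ont3$terms$obsolete[i] <- TRUE
  ont3$terms$replaced_by[i] <- ont3$terms$id[1]
  ont3 <- phyloanno:::new_ontology_graph(
    ont3$terms, ont3$edges[ont3$edges$child != fam$truth$term, ])
  r3 <- maintenance_check(model, fam$tree, ont3, rec)
  expect_true("term_merged" %in% r3$reason)
  expect_match(r3$action[r3$reason == "term_merged"], "rewrite")

  # delta 4: a supporting leaf dropped from the tree
  drop_leaf <- fam$truth$functional_leaves[1]
  # remove the leaf row and splice its parent out of the node table
  nodes <- fam$tree$nodes
  par <- nodes$parent[nodes$node_id == drop_leaf]
  sib <- setdiff(nodes$node_id[!is.na(nodes$parent) & nodes$parent == par],
                 drop_leaf)
  gp <- nodes$parent[nodes$node_id == par]
  nodes <- nodes[!(nodes$node_id %in% c(drop_leaf, par)), ]
  nodes$parent[nodes$node_id %in% sib] <- gp
  tree4 <- phyloanno:::new_gene_tree(fam$tree$family_id, nodes)
  r4 <- maintenance_check(model, tree4, fam$ontology, rec)
  expect_true("leaf_missing_from_tree" %in% r4$reason)
  idx <- stats::setNames("PTHROTHER", drop_leaf)
  r4b <- maintenance_check(model, tree4, fam$ontology, rec,
                           cross_family_index = idx)
  expect_true("leaf_moved_family" %in% r4b$reason)
})

test_that("report writers emit stable TSV and JSON", {
  tr <- fixture_tree()
  g <- chain_ontology()
  recs <- gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000003",
                     evidence_code = "IDA")
  m <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000003", supporting_leaves = list("HUM1")))
  fs <- family_stats(tr, recs, propagate(m, tr, g))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_family_stats(fs, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(names(back),
               c("family_id", "protein_count", "exp_proteins",
                 "exp_annotations", "exp_terms", "annotated_proteins",
                 "ibd_count", "iba_count", "inferred_terms"))
  expect_equal(back$iba_count, 2)
})
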