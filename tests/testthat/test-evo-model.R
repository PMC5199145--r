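test_that("assertion files parse into models and bad references error with line numbers", {
  tr <- fixture_tree()
  g <- chain_ontology()
  m <- parse_assertions("GAIN\tAN1\tGO:0000003\tHUM1", tr, g)
  expect_equal(nrow(m$gains), 1)
  expect_equal(nrow(m$losses), 0)
  m2 <- parse_assertions(paste("GAIN\tAN1\tGO:0000003\tHUM1",
                               "LOSS\tMUS1\tGO:0000003\tRAPID_DIVERGENCE",
                               "# a comment", sep = "\n"), tr, g)
  expect_equal(nrow(m2$losses), 1)
  expect_error(parse_assertions("GAIN\tAN1\tGO:0000003\tDRO1", tr, g),
               class = "phyloanno_reference_error", regexp = "ancestral")
  expect_error(parse_assertions("GAIN\tNOPE\tGO:0000003\tHUM1", tr, g),
               class = "phyloanno_reference_error", regexp = "line 1")
  expect_error(parse_assertions("LOSS\tMUS1\tGO:0000003\tBAD_CAUSE", tr, g),
               class = "phyloanno_enum_error")
})

test_that("obsolete terms in assertions are rewritten through replaced_by", {
  tr <- fixture_tree()
  txt <- paste(chain_obo_text(), "", "[Term]", "id: GO:0000044",
               "is_obsolete: true", "replaced_by: GO:0000003", sep = "\n")
  g <- parse_obo(txt)
  expect_message(m <- parse_assertions("GAIN\tAN1\tGO:0000044\tHUM1", tr, g),
                 regexp = "rewritten")
  expect_equal(m$gains$go_id, "GO:0000003")
})

test_that("assertion round-trips reproduce the model", {
  for (seed in c(4, 21)) {
    fam <- simulate_family(sim_params(n_leaves = 24, seed = seed))
    model <- random_model(fam, seed, max_gains = 3, max_losses = 3)
    txt <- write_assertions(model)
    m2 <- parse_assertions(txt, fam$tree, fam$ontology)
    expect_equal(dplyr::arrange(model$gains, go_id, node_id),
                 dplyr::arrange(m2$gains, go_id, node_id))
    expect_equal(dplyr::arrange(model$losses, go_id, node_id),
                 dplyr::arrange(m2$losses, go_id, node_id))
  }
})

test_that("validation accepts consistent models and names each violation", {
  tr <- fixture_tree()
  g <- chain_ontology()
  recs <- gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000003",
                     evidence_code = "IDA")
  usable <- filter_experimental(recs)$usable
  good <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000003", supporting_leaves = list("HUM1")))
  expect_equal(nrow(validate_model(good, tr, g, usable)), 0)

  # IEA support is never usable for a gain
  iea <- filter_experimental(gaf_record(db = "A", object_id = "HUM1",
                                        go_id = "GO:0000003",
                                        evidence_code = "IEA"))$usable
  v <- validate_model(good, tr, g, iea)
  expect_equal(v$rule, "unsupported_gain")

  nested <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = c("AN0", "AN1"), go_id = "GO:0000003",
    supporting_leaves = list("DRO1", "HUM1")))
  expect_true("nested_gain" %in% validate_model(nested, tr, g, NULL)$rule)

  stray_loss <- evolutionary_model("PTHRTEST",
    gains = tibble::tibble(node_id = "AN1", go_id = "GO:0000003",
                           supporting_leaves = list("HUM1")),
    losses = tibble::tibble(node_id = "DRO1", go_id = "GO:0000003",
                            cause = "UNSPECIFIED"))
  expect_true("loss_without_gain" %in% validate_model(stray_loss, tr, g, NULL)$rule)

  # losing a more general term blocks a specific gain, so this is valid
  general_loss <- evolutionary_model("PTHRTEST",
    gains = tibble::tibble(node_id = "AN1", go_id = "GO:0000003",
                           supporting_leaves = list("HUM1")),
    losses = tibble::tibble(node_id = "MUS1", go_id = "GO:0000002",
                            cause = "KEY_RESIDUES"))
  expect_equal(nrow(validate_model(general_loss, tr, g, usable)), 0)
})

test_that("presence sets apply the true-path rule in both directions", {
  tr <- fixture_tree()
  g <- chain_ontology()
  # positive evidence at a child term supports the parent term
  rec <- gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000003",
                    evidence_code = "IDA")
  ps <- presence_sets(tr, rec, g, "GO:0000002")
  expect_equal(ps$P, "HUM1")
  # negation at a parent term excludes the child term
  rec2 <- gaf_record(db = "B", object_id = "MUS1", go_id = "GO:0000002",
                     evidence_code = "IMP", qualifier = "NOT")
  ps2 <- presence_sets(tr, rec2, g, "GO:0000003")
  expect_equal(ps2$N, "MUS1")
  # conflicting evidence goes to P with a warning
  both <- dplyr::bind_rows(
    gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000003",
               evidence_code = "IDA"),
    gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000002",
               evidence_code = "IMP", qualifier = "NOT"))
  expect_warning(ps3 <- presence_sets(tr, both, g, "GO:0000003"),
                 regexp = "conflicting")
  expect_equal(ps3$P, "HUM1")
  expect_equal(ps3$conflicts, "HUM1")
  expect_length(ps3$N, 0)
})

test_that("presence sets equal a brute-force scan on random fixtures", {
  for (seed in c(6, 13, 27)) {
    p <- sim_params(n_leaves = 30, p_observe = 0.7, p_false_positive = 0.3,
                    p_negative = 0.6, seed = seed)
    fam <- simulate_family(p)
    rec <- simulate_annotations(fam$tree, fam$ontology, fam$truth, p)
    for (q in unique(c(fam$truth$term, fam$ontology$terms$id[1]))) {
      got <- suppressWarnings(presence_sets(fam$tree, rec, fam$ontology, q))
      want <- oracle_presence_sets(fam$tree, rec, fam$ontology, q)
      expect_equal(got$P, want$P)
      expect_equal(got$N, want$N)
    }
  }
})

test_that("the Dollo suggester anchors gains at the MRCA and places forced losses", {
  tr <- fixture_tree()
  g <- chain_ontology()
  s1 <- suggest_model(tr, P = c("HUM1", "MUS1"), N = character(),
                      go_id = "GO:0000002")
  expect_equal(s1$model$gains$node_id, "AN1")
  expect_equal(nrow(s1$model$losses), 0)
  expect_false(s1$single_support)
  expect_equal(s1$alternates, "AN0")

  s2 <- suggest_model(tr, P = c("HUM1", "DRO1"), N = "MUS1",
                      go_id = "GO:0000002")
  expect_equal(s2$model$gains$node_id, "AN0")
  expect_equal(s2$model$losses$node_id, "MUS1")
  expect_equal(s2$model$losses$cause, "UNSPECIFIED")

  s3 <- suggest_model(tr, P = "HUM1", N = character(), go_id = "GO:0000002")
  expect_true(s3$single_support)
  expect_error(suggest_model(tr, P = character(), go_id = "GO:0000002"),
               class = "phyloanno_no_evidence")
})

test_that("absence of annotation never triggers a loss", {
  tr <- fixture_tree()
  s <- suggest_model(tr, P = c("HUM1", "DRO1"), N = character(),
                     go_id = "GO:0000002")
  # MUS1 is unobserved, not negated: no loss may be suggested
  expect_equal(nrow(s$model$losses), 0)
})

test_that("propagation reproduces the worked fixture exactly", {
  tr <- fixture_tree()
  g <- chain_ontology()
  m <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000003", supporting_leaves = list("HUM1")))
  inf <- propagate(m, tr, g)
  expect_equal(inf$evidence, c("IBD", "IBA", "IBA"))
  expect_equal(inf$target, c("AN1", "HUM1", "MUS1"))
  expect_false("DRO1" %in% inf$target)
  expect_true(all(inf$gain_node == "AN1"))
  expect_true(all(vapply(inf$supporting_leaves, identical, logical(1), "HUM1")))

  with_loss <- evolutionary_model("PTHRTEST",
    gains = m$gains,
    losses = tibble::tibble(node_id = "MUS1", go_id = "GO:0000003",
                            cause = "RAPID_DIVERGENCE"))
  inf2 <- propagate(with_loss, tr, g)
  expect_equal(sort(paste(inf2$evidence, inf2$target)),
               sort(c("IBD AN1", "IBA HUM1", "IRD MUS1")))
  expect_true(inf2$negated[inf2$evidence == "IRD"])
})

test_that("invalid models are rejected with the violations attached", {
  tr <- fixture_tree()
  g <- chain_ontology()
  bad <- evolutionary_model("PTHRTEST", gains = tibble::tibble(
    node_id = "AN1", go_id = "GO:0000003", supporting_leaves = list("DRO1")))
  err <- tryCatch(propagate(bad, tr, g), condition = function(c) c)
  expect_s3_class(err, "phyloanno_invalid_model")
  expect_equal(err$violations$rule, "gain_not_ancestral")
})

test_that("term-downward loss blocking follows the ontology", {
  tr <- fixture_tree()
  g <- chain_ontology()
  # loss of the general term blocks propagation of the specific gain
  m <- evolutionary_model("PTHRTEST",
    gains = tibble::tibble(node_id = "AN1", go_id = "GO:0000003",
                           supporting_leaves = list("HUM1")),
    losses = tibble::tibble(node_id = "MUS1", go_id = "GO:0000002",
                            cause = "KEY_RESIDUES"))
  inf <- propagate(m, tr, g)
  expect_false("MUS1" %in% inf$target[inf$evidence == "IBA"])
  expect_equal(inf$evidence[inf$target == "MUS1"], "IKR")
  expect_equal(inf$go_id[inf$target == "MUS1"], "GO:0000002")
})

test_that("propagation equals the path-walking oracle on random instances", {
  for (seed in 31:40) {
    fam <- simulate_family(sim_params(n_leaves = sample(8:40, 1), seed = seed))
    model <- random_model(fam, seed)
    inf <- propagate(model, fam$tree, fam$ontology)
    for (i in seq_len(nrow(model$gains))) {
      gnode <- model$gains$node_id[i]
      gterm <- model$gains$go_id[i]
      blocking <- oracle_blocking_losses(fam$tree, fam$ontology, model,
                                         gnode, gterm)
      want <- oracle_iba_targets(fam$tree, gnode, blocking)
      got <- inf$target[inf$evidence == "IBA" & inf$gain_node == gnode &
                          inf$go_id == gterm]
      expect_setequal(got, want)
      expect_equal(sum(inf$evidence == "IBD" & inf$gain_node == gnode &
                         inf$go_id == gterm), 1)
    }
  }
})

test_that("propagation is idempotent and stably ordered", {
  fam <- simulate_family(sim_params(n_leaves = 24, seed = 8))
  model <- random_model(fam, 8)
  expect_identical(propagate(model, fam$tree, fam$ontology),
                   propagate(model, fam$tree, fam$ontology))
})

test_that("conflicts are reported for negated-under-IBA and evidence-under-loss", {
  tr <- fixture_tree()
  g <- chain_ontology()
  m <- evolutionary_model("PTHRTEST",
    gains = tibble::tibble(node_id = "AN0", go_id = "GO:0000003",
                           supporting_leaves = list("HUM1")),
    losses = tibble::tibble(node_id = "MUS1", go_id = "GO:0000003",
                            cause = "UNSPECIFIED"))
  recs <- dplyr::bind_rows(
    gaf_record(db = "A", object_id = "HUM1", go_id = "GO:0000003",
               evidence_code = "IDA"),
    # NOT at the parent term conflicts with IBA to the child term
    gaf_record(db = "C", object_id = "DRO1", go_id = "GO:0000002",
               evidence_code = "IMP", qualifier = "NOT"),
    # positive evidence under the blocked subtree
    gaf_record(db = "B", object_id = "MUS1", go_id = "GO:0000003",
               evidence_code = "IDA"))
  inf <- propagate(m, tr, g)
  cf <- detect_conflicts(inf, recs, tr, m, g)
  expect_setequal(cf$rule, c("negative_evidence_under_propagation",
                             "experimental_evidence_under_loss"))
  expect_equal(cf$leaf[cf$rule == "negative_evidence_under_propagation"], "DRO1")
  expect_equal(cf$leaf[cf$rule == "experimental_evidence_under_loss"], "MUS1")
  # a consistent fixture yields no conflicts
  cf2 <- detect_conflicts(inf, recs[1, ], tr,
                          evolutionary_model("PTHRTEST", m$gains), g)
  expect_equal(nrow(cf2), 0)
})

test_that("GAF export encodes provenance per the phylogenetic conventions", {
  tr <- fixture_tree()
  g <- chain_ontology()
  m <- evolutionary_model("PTHRTEST",
    gains = tibble::tibble(node_id = "AN1", go_id = "GO:0000003",
                           supporting_leaves = list("HUM1")),
    losses = tibble::tibble(node_id = "MUS1", go_id = "GO:0000003",
                            cause = "RAPID_DIVERGENCE"))
  gaf <- inferred_to_gaf(propagate(m, tr, g), tr, g, date = "20260101")
  ibd <- gaf[gaf$evidence_code == "IBD", ]
  expect_equal(ibd$db, "PANTHER")
  expect_equal(ibd$object_id, "PTHRTEST:AN1")
  expect_equal(ibd$with_from[[1]], "A:HUM1")
  iba <- gaf[gaf$evidence_code == "IBA", ]
  expect_equal(iba$object_id, "HUM1")
  expect_equal(iba$with_from[[1]][1], "PANTHER:PTHRTEST:AN1")
  expect_equal(iba$references[[1]], "GO_REF:0000033")
  ird <- gaf[gaf$evidence_code == "IRD", ]
  expect_true(ird$negated)
  expect_equal(ird$qualifier, "NOT")
  # the export is valid GAF
  expect_no_error(write_gaf(gaf))
})

test_that("IBA lineages crossing a horizontal transfer are tagged", {
  txt <- paste0("((A:L1,B:L2)[&&NHX:ID=AN1:Ev=H],C:L3)[&&NHX:ID=AN0:Ev=S];")
  tr <- parse_tree(txt, "X")
  g <- chain_ontology()
  m <- evolutionary_model("X", gains = tibble::tibble(
    node_id = "AN0", go_id = "GO:0000002", supporting_leaves = list("L3")))
  inf <- propagate(m, tr, g)
  via <- stats::setNames(inf$via_hgt, inf$target)
  expect_true(all(via[c("AN1", "L1", "L2")]))
  expect_false(via[["L3"]])
})
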