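Package: phyloanno
Title: Phylogenetic Propagation of Gene Ontology Annotations over Gene
    Family Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the gain and loss of gene functions on a rooted gene
    family tree and propagates experimentally supported Gene Ontology
    (GO) annotations from ancestral nodes to descendants. Curator-style
    gain/loss models (Dollo parsimony: one gain, multiple losses) are
    represented explicitly, validated against experimental evidence,
    suggested automatically from presence/absence sets, and applied to
    produce IBD ("inferred from biological descendant") annotations at
    gain nodes and IBA ("inferred from biological ancestor") annotations
    at their descendants, with IKR/IRD negated annotations at loss
    nodes. Includes readers and writers for OBO ontologies, NHX-tagged
    Newick gene trees, GAF 2.1/2.2 annotation files and a curator
    assertion format; quality-assurance flags for over-annotation-prone
    evidence; family-level annotation statistics; maintenance checks
    against updated inputs; and a synthetic-family simulator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
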