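---
title: "Phylogenetic propagation of GO annotations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic propagation of GO annotations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloanno)
library(tibble)
```

## The problem

Experimental GO annotation is sparse and uneven: in a typical protein
family only on the order of 10% of members carry any experimentally
supported annotation, and those annotations concentrate in a handful of
model organisms. Phylogenetic annotation turns this sparse evidence into
family-wide coverage by reasoning about when functions arose and were
lost on the family tree. The procedure has two steps:

1. **Model building.** Given the distribution of experimentally
   characterized genes, an explicit model of the evolution of each
   function is asserted: the function was *gained* at a specific
   ancestral node (the most recent common ancestor of the supported
   genes, unless the curator argues otherwise) and possibly *lost* along
   specific descendant lineages.
2. **Propagation.** The model is applied mechanically: the gain node
   receives an IBD annotation ("inferred from biological descendant",
   pointing at the supporting experimental genes), every descendant
   outside a lost lineage receives an IBA annotation ("inferred from
   biological ancestor", pointing back at the gain node), and each loss
   node receives a negated annotation with evidence IKR (key residues
   lost) or IRD (rapid divergence).

The evidence trail is explicit in both directions, which is what makes
the output auditable and maintainable: every inferred annotation names
the experimental records it rests on.

## The inference model

### Evidence classes

Only non-negated records with an experimental evidence code (default
`EXP, IDA, IPI, IMP, IGI, IEP`) may support a gain. High-throughput
codes (`HDA, HMP, HGI, HEP, HTP`) are excluded by default: HTP
experiments — especially localization screens — carry a high
false-positive rate (a nominal ~1% per study, additive across the many
studies integrated into GO), and transient residence in the ER/Golgi
during biosynthesis is routinely mis-reported as functional
localization. The HTP set is configurable (`evidence_config()`) because
the boundary of "high throughput" is policy, not algorithm. Curated
non-experimental codes (`ISS`, `TAS`, `IC`, `IEA`, ...) are never usable
as gain support. NOT-qualified experimental records are not discarded:
they are the negative-evidence stream that justifies loss events.

### True-path semantics

Closure is computed over `is_a` and `part_of` edges, the standard
GO annotation-propagation convention. `regulates`-type relations are
deliberately ignored: closing over them would import exactly the
indirect, downstream roles that the evidence filter tries to keep out.
The true-path rule is applied in both directions:

* a positive record to a term supports every *ancestor* of that term
  (evidence for a specialization is evidence for the general function),
  so the presence set for term $t$ collects leaves annotated to $t$ or
  any descendant of $t$;
* a NOT record to a term denies every *descendant* (a gene lacking the
  general capability lacks its specializations), so the negation set for
  $t$ collects leaves with NOT records to $t$ or any ancestor of $t$.

A leaf with both kinds of evidence is assigned to the presence set and
flagged as a conflict for curator review — positive direct evidence is
treated as stronger than a negation inherited from a more general term.

### Dollo suggestion

`suggest_model()` implements single-gain Dollo parsimony: a function is
gained once and may be lost many times. Given presence set $P$ and
negation set $N$ for a term:

* the gain is anchored at $g = \mathrm{MRCA}(P)$ — the most recent node
  from which a single gain can reach every supported gene;
* losses are placed at the *maximal* subtrees below $g$ that contain at
  least one $N$ leaf and no $P$ leaf.

This loss set is minimum-cardinality among all loss sets that exclude
every $N$ leaf below $g$ and no $P$ leaf: the maximal qualifying
subtrees are pairwise disjoint, each needs at least one loss, and one
loss at each subtree root suffices. The test suite verifies this against
exhaustive search on trees of up to 12 leaves.

Two asymmetries are deliberate. **Absence of annotation is never
absence of function**: an unobserved leaf triggers no loss. Only
negative evidence (or a manual curator assertion, e.g. from key-residue
inspection) places a loss. And **a single-support gain** ($|P| = 1$) is
legal but flagged: one characterized gene is weak grounds for claiming
the function is conserved across a clade, so propagation from such gains
is discouraged rather than forbidden. Ancestors of $g$ are reported as
legal but less parsimonious alternative gain points; the curator may
prefer one when outgroup biology argues for an earlier origin.

### Propagation and blocking

For each gain $(g, t)$, IBA reaches every strict descendant of $g$ not
inside a blocked subtree. A loss $(v, t')$ blocks term $t$ iff $t' = t$
or $t$ is an ontology descendant of $t'$ — losing a general capability
entails losing its specializations (term-downward blocking). The
reverse direction does not block: losing a specialization says nothing
about sibling specializations or the general function. Whether a loss
should also block *sibling-related* terms is left unimplemented, since
no principled rule exists without curator input.

Related design choices, each of which was genuinely open:

* **Duplication nodes do not block propagation.** Annotation across
  duplications is routine (paralog pairs commonly retain core
  functions); where subfunctionalization occurred, the curator asserts
  explicit losses.
* **Horizontal-transfer nodes propagate like speciation nodes** but
  every IBA whose lineage crosses one is tagged `via_hgt`, so reports
  can surface them; there is no established convention for gain/loss
  semantics across HGT.
* **Independent gains of the same term on disjoint lineages are
  allowed** (convergent acquisition); nested gains of the same term are
  invalid, since the deeper "gain" would be vacuous under the ancestral
  one.
* **Leaves with experimental records still receive IBA**: the inferred
  and experimental layers are kept separate so that each can be audited,
  and the `new_annotations()` accounting subtracts experimentally
  supported pairs afterwards.
* Output ordering is (gain term, preorder index), and ties among
  maximal blocked subtrees are all reported; output is byte-stable.

### Validation

A model must pass `validate_model()` before propagation: every gain
dominates its support; every supporting leaf carries at least one usable
experimental record to the gain term or an ontology descendant; every
loss lies strictly below a gain it blocks; no same-term gains are
nested. Violations are returned as data (a tibble), not exceptions —
they are the curator's worklist. `detect_conflicts()` runs after
propagation and reports IBA landing on negated evidence and experimental
evidence inside lost subtrees; conflicts are findings, never errors.

## Maintenance

The inputs move constantly under a published model: terms are obsoleted
or merged, primary annotations are retracted, trees are rebuilt, and
sequences move between families. `maintenance_check()` re-validates each
gain against updated inputs and classifies what broke
(`term_obsoleted`, `term_merged` with a proposed `replaced_by` rewrite,
`support_record_removed` per affected leaf, `leaf_missing_from_tree`, or
`leaf_moved_family` when a cross-family index locates the sequence).
Obsolete terms are rewritten through `replaced_by` only; `consider:`
suggestions are ambiguous and left to the curator.

## The synthetic-family generator

`simulate_family()` and `simulate_annotations()` define the testbed:
all correctness claims in the test suite are statements about data from
this generator. What it emulates, and its defaults:

| parameter | default | rationale |
|---|---|---|
| `n_leaves` | 64 | a mid-sized PANTHER-like family |
| `p_duplication` | 0.2 | reconciled family trees are duplication-rich |
| `p_loss` | 0.1 | per-edge loss probability below the gain |
| `p_observe` | 0.6 | fraction of truly functional genes with direct experimental evidence, for a moderately studied function |
| `p_false_positive` | 0.01 | the ~1% false-discovery rate conventionally accepted in publication |
| `p_negative` | 0.1 | negative results are rarely published |
| `n_terms` | 20 | ontology large enough for nontrivial closure |

Trees are grown by sequential leaf attachment (each new leaf splits a
uniformly chosen existing leaf — a Yule-type process), events are drawn
i.i.d., and the ontology is a random DAG whose target term is guaranteed
an ancestor and a descendant. Spurious records use IMP — the archetypal
phenotype-noise code — so the QA-flag rules and the inference tests can
share fixtures; genuine observations use IDA, half the time recorded at
a random descendant of the true term, mirroring real corpora where
evidence is often more specific than the propagated term. Seeding is by
named substream: each generation stage draws from its own derived seed,
so outputs are bit-identical under a fixed seed and adding a stage never
perturbs earlier draws.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: trees are not reconciled against a species
tree (no correlated duplication/loss rates, no realistic taxon
sampling); annotation noise is i.i.d. rather than study-correlated
(one HTP paper annotating hundreds of genes at once); the ontology is
far smaller than GO; and there is exactly one true gain per term
(multi-gain scenarios are composed from disjoint subtrees in tests, not
generated). Recovery rates measured here are therefore statements about
the engine's logic, not predictions of curation accuracy on PANTHER
families.

## Verification strategy and problem sizes

Every non-trivial computation is checked against an independent oracle
implemented differently from the production path: ontology closure
against igraph reachability; MRCA against a count-and-intersect scan;
IBA target sets against per-node path walking; the Dollo loss set
against exhaustive subset search; statistics against plain-loop
recounts. The full-scale property runs use 500 random families (up to
~200 nodes, up to 5 gains and 5 losses) for propagation, 300 trees of at
most 12 leaves for Dollo minimality (the exhaustive oracle is
exponential), 50 replicates for the perfect-information recovery check
(provable: with no losses, full observation and no noise, the MRCA of
the functional leaves *is* the gain node), and 200 replicates per point
on the observation-probability grid `1.0, 0.8, 0.6, 0.4`. The grid uses
common random numbers — the same simulated families at every coverage
level — which makes the monotone-degradation property exact rather than
merely statistical: an observed subset's MRCA can only move down-tree.
`scripts/acceptance.R` re-runs all of these from scratch and writes the
measured rates as JSON.

## Numerical and formatting choices

Branch lengths are parsed and preserved but unused by inference (the
method is event-based, not clock-based); writers emit them with 6
decimals, and the simulator snaps its lengths to that grid so
serialization round-trips bit-exactly. Newick/NHX output sorts NHX keys;
GAF output is sorted by (object, term, evidence); OBO output sorts terms
and edge lines — all writers are deterministic so identical inputs give
byte-identical outputs. Unrooted trees are rejected (gain/loss direction
needs a root); polytomies are accepted. The GAF writer emits dialect 2.1
(qualifier optional, maximal reader compatibility); the reader accepts
2.1 and 2.2. Leaf labels are `DB:ACC`; a trailing `:number` on a label
token is interpreted as a branch length, which is unambiguous for
database-qualified accessions.

## A worked example

```{r worked}
ontology <- parse_obo(paste(
  "[Term]", "id: GO:0000001", "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "namespace: biological_process",
  "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000003", "namespace: biological_process",
  "is_a: GO:0000002", sep = "\n"))
tree <- parse_tree(paste0(
  "((A:HUM1[&&NHX:S=HUMAN],B:MUS1[&&NHX:S=MOUSE])[&&NHX:ID=AN1:Ev=D],",
  "C:DRO1[&&NHX:S=DROME])[&&NHX:ID=AN0:Ev=S];"), "PTHRTEST")

model <- evolutionary_model("PTHRTEST",
  gains = tibble(node_id = "AN1", go_id = "GO:0000003",
                 supporting_leaves = list("HUM1")),
  losses = tibble(node_id = "MUS1", go_id = "GO:0000003",
                  cause = "RAPID_DIVERGENCE"))
propagate(model, tree, ontology)[, c("target", "go_id", "evidence", "negated")]
```

One gain at the duplication node gives one IBD there and IBA at the two
leaves below it; adding the loss at `MUS1` replaces its IBA with a
negated IRD row. `DRO1`, outside the gain clade, is untouched.

## Known limitations

Taxon-range reasoning ("this process does not occur outside metazoa") is
not formalized; the assertion format carries explicit curator losses
instead, and a per-term taxon allow/deny list in configuration is the
natural extension point. Probabilistic ancestral-state reconstruction
and branch-length-aware models are out of scope by design: the engine's
contract is to apply an explicit, auditable curator model, not to infer
one statistically. The tool suggests; it does not decide.
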