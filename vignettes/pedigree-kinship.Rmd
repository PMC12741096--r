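---
title: "Pedigree graphs, n-degree relatives, and path-counting kinship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree graphs, n-degree relatives, and path-counting kinship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindred)
```

## The problem

Register- and biobank-scale genetic studies record ancestry as *trio data*:
one row per individual carrying the individual's ID and the IDs of the
father and the mother. Family-based analyses — family history indicators,
family-based liability models, mixed models with relatedness covariance —
need the opposite view: for a focal individual (the *proband*), the set of
all relatives up to some degree, their degrees of relatedness, a kinship
matrix over the family, and human-readable relationship labels. kindred
turns population-level trio tables into a graph on which all of these are
neighbourhood operations.

## The pedigree graph

`prepare_graph()` builds a mixed graph:

* one **directed parental edge** per non-missing parent reference
  (parent → child, role-tagged `father` or `mother`);
* one **full-sibling edge** per unordered pair of individuals sharing both
  (non-missing) parents, stored once per pair and traversed in both
  directions.

The sibling edges are what make plain graph distance coincide with the
classical *degree of relatedness* on loop-free pedigrees: parent 1,
grandparent / half-sibling / aunt-uncle 2, first cousin /
great-grandparent 3, and so on. Without them full siblings would sit two
steps apart (up to a parent and back down).

Three further construction rules matter in register data:

* Parents referenced without a row of their own become founder nodes —
  registers truncate ascending lineages, and dropping such references would
  silently shrink families.
* Individuals with no parents, children, or siblings are kept as isolated
  nodes, so population counts remain correct.
* Every non-ID column of the input (sex included) is attached verbatim to
  the node, with no type coercion; downstream family extraction preserves
  these attributes, which is what makes the graph usable to carry
  phenotypes or weights per family member.

Cyclic parentage (an individual being their own ancestor) is a hard error,
not a warning: every algorithm below assumes ancestor relations are
well-founded. `validate_graph()` re-derives the sibling-edge rule and the
one-father/one-mother constraint and reports violations without erroring,
for auditing hand-edited graphs.

Missing parent IDs default to the codes `""`, `"NA"`, and `"0"`. `"0"` is
the PLINK convention but can be a legitimate ID elsewhere, so the code set
is a `read_trios()` argument rather than a constant.

## n-degree families

`get_family_graphs()` takes the ego (neighbourhood) graph of radius *n*
around each proband, ignoring edge direction. Direction-blind traversal is
deliberate: descendants are relatives too, and the subgraph must contain
them. Degrees are shortest-path distances; within a radius-*n* ball the
in-ball distances equal the global ones, so no second pass over the full
graph is needed.

Plain neighbourhood semantics include *affines*: the co-parent of a
proband's child is two undirected steps away and therefore a degree-2
member. They are kept by default — membership is defined purely by
neighbourhood distance — and the kinship and labelling layers assign them 0
and `Unrelated` respectively. `blood_only = TRUE` filters them out when a
strictly consanguine family is wanted.

## Kinship by path counting

`get_kinship()` scores every pair in a (sub)graph as

$$k_{ij} = C \cdot 0.5^{d_{ij}}$$

where $d_{ij}$ is the length of the shortest *genealogically valid* path
between $i$ and $j$ and $C$ is a scalar (default 1; e.g. a heritability). A
valid path ascends child-to-parent, crosses at most one full-sibling edge
at its apex, then descends — the "up, optionally across, down" shape that
passes through a most recent common ancestor configuration. Raw undirected
distance is deliberately **not** used: it would give co-parents kinship
0.25 through their shared child, a path that carries no shared ancestry.

The implementation computes, per individual, the map of ancestors-or-self
with their ascent distances (one upward BFS over parental edges), then
takes

$$d_{ij} = \min\Big(\min_{a}\; u_i(a) + u_j(a),\;\;
\min_{\{s,t\}\,\text{sib}}\; u_i(s) + 1 + u_j(t)\Big)$$

over common ancestors $a$ and full-sibling edges $\{s,t\}$ with $s$
ancestral-or-self to $i$ and $t$ to $j$. The result is independent of
traversal order; pairs with no configuration are structural zeros (the
sparse triplet output simply omits them, since population graphs are mostly
unrelated pairs).

Properties worth knowing before using the matrix in a model:

* On **loop-free** pedigrees — no pair related through two distinct
  ancestral couples — $0.5^{d}$ equals exactly twice the classical kinship
  coefficient $\varphi$ of the recursion
  $\varphi(a,b)=\tfrac12(\varphi(\mathrm{fa}(a),b)+\varphi(\mathrm{mo}(a),b))$.
  The test suite asserts this to $10^{-12}$ against an independent
  implementation of the recursion.
* Under pedigree loops it is a **lower bound**: double first cousins score
  $0.5^3 = 0.125$ while $2\varphi = 0.25$. The divergence is a documented,
  tested property, not a bug.
* The estimator is **not inbreeding-aware**: the diagonal is $C$
  regardless of ancestral consanguinity, and monozygotic twins are plain
  full siblings. For consanguineous families, reconstruct trios with
  `graph_to_trio()` and use an inbreeding-aware calculator.
* Distances are computed **within the supplied graph**. For a
  neighbourhood subgraph that truncates a connecting ancestor (e.g. a
  shared great-grandparent outside the radius), the truncated connection
  does not contribute. This matches the "kinship of the individuals present
  in the graph" contract; compute on the full graph when that matters.

## Relationship labels

`get_relations()` classifies each family member by the *(up, down)*
generations to the selected MRCA configuration plus a full/half flag, and
`classify_pair()` maps that triple to a code: `Pa`/`GPa`/`GGPa`…,
`Ch`/`GCh`…, `Sib`/`HSib`, piblings `Pib`/`GPib`… (parent's sibling),
niblings `Nib`/`GNib`…, and cousins `xC` with removal `xCyR` (order
`min(up,down) − 1`, removal `|up − down|`). Codes are sex-neutral;
descriptions specialise to mother/father, aunt/uncle, etc. when a `sex`
attribute is present.

Two rules required a decision the contract left open:

* **Tie-breaking.** Several MRCA configurations can share the minimal
  implied degree. Among them the most *horizontal* one (largest
  `min(up, down)`) is chosen, then full before half. This is the simplest
  formalisation of favouring horizontal family members; on loop-free
  pedigrees the tie never fires, so it only affects looped families.
* **Caps.** Configurations ascending more than 6 generations on the
  proband's side (beyond the great-great-great-great-grandparents), or of
  implied degree above 9, are bucketed as `Distant` rather than named. The
  caps are `max_up` / `max_degree` arguments; the label inventory below
  them is this package's own taxonomy and is enumerated by
  `relation_codes()`.

Degree consistency is an invariant: on loop-free pedigrees the degree
implied by the label (`up + down − 1` for full collaterals, `up + down`
otherwise) equals the graph-distance degree of the member, and the suite
checks reciprocity (your `Pib` sees you as `Nib`, cousin codes are
symmetric).

## Summaries and the grid figure

`relation_summary()` counts each code over the row-bound relation tables
of many probands and reports totals and means per proband (`Self` rows are
excluded; canonical codes absent from the data are zero-filled so
comparisons across cohorts line up). `relation_grid_figure()` renders the
classical consanguinity-chart grid — rows are generations up, columns
generations down, each cell `CODE total (mean)` with the mean at 3
decimals. `Unrelated` and `Distant` appear in the summary table but not in
the figure. Rendering is deterministic for a fixed summary.

```{r, eval = FALSE}
pop <- make_random_pedigree(n_founder_couples = 200, n_generations = 4,
                            sibship_lambda = 2.4, half_sib_rate = 0.1,
                            seed = 1)
g <- prepare_graph(pop)
set.seed(2)
fams <- get_family_graphs(g, sample(pop$id, 500), degree = 3)
rel <- dplyr::bind_rows(lapply(fams, get_relations))
relation_grid_figure(relation_summary(rel, 500), "relations.svg")
```

## The synthetic pedigree generator

`make_random_pedigree()` exists so that every algorithm is testable
against exact oracles without external data. It is deliberately a
*structural* model, not a demographic one:

* founder couples seed generation 0; sibship sizes are zero-truncated
  Poisson (`sibship_lambda`, default 2.4 — roughly replacement-level
  completed family size);
* with probability `half_sib_rate` (default 0.1) a parent re-partners once
  with a new unrelated partner, creating half-sibships;
* under `loop_free = TRUE` every mate is a fresh immigrant, which
  guarantees no pair is related through two distinct ancestral couples —
  exactly the precondition under which path-counting kinship equals the
  classical recursion, making the generator the test bed for that
  equivalence. With `loop_free = FALSE`, 30% of children instead marry
  within their generation across sibships, producing the loops (double
  first cousins and worse) on which the estimator's lower-bound behaviour
  is exercised.

What it does **not** emulate: overlapping generations, assortative or
age-structured mating, migration, mortality, or realistic sibship-size
dispersion. Tests passing on these pedigrees therefore certify the graph
algorithms, not any demographic realism; on real register data the same
code paths run, but family sizes and loop frequencies will differ.

`canonical_fixtures()` complements the generator with five hand-built
families (nuclear, half-sib, a 16-person four-generation family, double
first cousins, isolated singletons), each shipping a sidecar of
hand-verified (pair, distance, kinship, label) assertions used across the
test suite.

## Numerical and degenerate-input choices

* Distances are exact integers; kinship values are powers of 0.5 and the
  classical-recursion comparison is asserted to $10^{-12}$ (pure binary
  fractions, so the only tolerance needed is guard against accumulation in
  the oracle).
* `Inf` encodes "no genealogical path" at the distance level; it becomes a
  structural 0 in kinship output.
* Empty tables, header-only files, isolated probands, and all-zero
  summaries are all defined inputs with tested behaviour rather than
  errors.
* `graph_to_trio()` errors on an unsexed parent by default
  (`on_ambiguity = "set_missing"` downgrades the link to missing) and
  always errors on two same-sex parents of one child: silent data loss
  loses to loud failure.
* The generator restores the caller's RNG state; all CLI randomness flows
  from `--seed`.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: 50 loop-free
pedigrees of up to 200 individuals for the kinship/BFS oracle
equivalences, and one register-scale population of roughly 29,000
individuals (200 founder couples, 4 generations) from which 500 random
probands get degree-3 families, kinship matrices, and relation summaries.
On one core the full population pass takes well under a minute.

## Limitations

* Kinship is genealogical only — no marker-based (genomic) kinship, no
  X-linked variant, no inbreeding adjustment (Karigl-style coefficients
  are out of scope by design).
* Affinal relations (in-laws, step-relations) and composite labels
  ("double first cousin") are not named; such members surface as
  `Unrelated` or under their single best consanguine label.
* GEDCOM and other genealogy interchange formats are not read; trio
  CSV/TSV and PLINK `.fam` are the interfaces.
* The label inventory beyond degree 9 is intentionally absent; deep
  relations are summarised as `Distant`.
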