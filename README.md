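# kindred

Family detection from population-level trio data: pedigree graphs,
n-degree relatives, path-counting kinship matrices, and relationship
labelling, in R.

## Who this is for

Register- and biobank-based genetic epidemiology records ancestry as
**trio data** — one row per individual with the IDs of the father and the
mother. Analyses that condition on family (family-history indicators,
family-based liability models, mixed models with relatedness covariance)
need the inverse view: for each proband, all relatives up to degree *n*,
their kinship matrix, and their relationship labels. Existing pedigree
tools either stop at second-degree relatives, return whole connected
components, or require chained pre/post-processing. kindred does the
extraction, scoring, labelling, and round-tripping in one package built on
igraph, and scales to populations of tens of thousands of individuals on a
laptop core.

## The model

`prepare_graph()` turns a trio table into a mixed graph: directed parental
edges (parent → child, role-tagged) plus one **full-sibling edge** per pair
sharing both parents. Sibling edges make undirected graph distance equal
the classical degree of relatedness (parent 1; grandparent, half-sibling,
aunt/uncle 2; first cousin 3; …). `get_family_graphs()` then extracts each
proband's radius-*n* neighbourhood.

Kinship is estimated by path counting:

```
k(i, j) = C · 0.5^d(i,j)
```

where `d(i,j)` is the shortest *genealogically valid* path — ascend
child-to-parent, cross at most one full-sibling edge at the apex, descend —
through a most recent common ancestor configuration, and `C` is a scalar
(default 1, e.g. a heritability). On loop-free pedigrees `0.5^d` equals
twice the classical kinship coefficient exactly; under loops it is a lower
bound (double first cousins: 0.125 vs 0.25), and it is not
inbreeding-aware. Affines (co-parents) get 0: their connecting path
descends before ascending and is not genealogical.

`get_relations()` labels each member from its (generations up, generations
down, full/half) MRCA configuration — `Pa`, `GPa`, `Sib`, `HSib`, `Pib`
(pibling: parent's sibling), `Nib`, `1C`, `1C2R` (first cousin twice
removed), … — and `relation_summary()` / `relation_grid_figure()` aggregate
totals and means per proband into a consanguinity-chart grid.
`graph_to_trio()` reconstructs trio tables from any (sub)graph so
identified families flow back into other pedigree tools.

## Worked example

The bundled 16-person four-generation fixture around proband `p`:

```r
library(kindred)
fx <- canonical_fixtures()
g <- prepare_graph(fx$four_generation$trios)
fam <- get_family_graphs(g, "p", degree = 3)[["p"]]
get_relations(fam)
```

```
   proband_id member_id    up  down fullness       code      description  degree
 1 p          p             0     0 not_applicable Self      self              0
 2 p          fa            1     0 not_applicable Pa        father            1
 3 p          mo            1     0 not_applicable Pa        mother            1
 4 p          sib           1     1 full           Sib       sister            1
 5 p          gf            2     0 not_applicable GPa       grandfather       2
 6 p          gm            2     0 not_applicable GPa       grandmother       2
 7 p          hsib          1     1 half           HSib      half brother      2
 8 p          pib           2     1 full           Pib       uncle             2
 9 p          cous          2     2 full           1C        first cousin      3
10 p          ggf           3     0 not_applicable GGPa      great-grand…      3
11 p          ggm           3     0 not_applicable GGPa      great-grand…      3
12 p          gpib          3     1 full           GPib      grand-pibli…      3
13 p          step         NA    NA not_applicable Unrelated no genealog…     NA
```

Each member is placed by generations up/down to the most recent common
ancestor: the paternal half-sibling is a half relation at degree 2, the
first cousin a full relation at degree 3, and the father's second partner
(`step`) — though inside the degree-3 neighbourhood — has no genealogical
path and is labelled `Unrelated`. The kinship matrix over the same family:

```r
round(get_kinship(fam)[c("p", "fa", "hsib", "cous"), c("p", "fa", "hsib", "cous")], 4)
```

```
         p   fa  hsib  cous
p    1.000 0.50 0.250 0.125
fa   0.500 1.00 0.500 0.250
hsib 0.250 0.50 1.000 0.125
cous 0.125 0.25 0.125 1.000
```

i.e. `0.5^1` for parent–child, `0.5^2` for half-siblings, `0.5^3` for
first cousins; `step`'s row (not shown) is all zeros.

At population scale: `make_random_pedigree(200, 4, seed = 1)` simulates
roughly 29,000 individuals; building the graph, extracting degree-3
families for 500 random probands, and computing all 500 kinship matrices
takes a few seconds each on one core.

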