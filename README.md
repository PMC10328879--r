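# pdspace

Phylogenetic diversity (PD) measures the biodiversity of a set of species as
the sum of the branch lengths of their rooted phylogenetic tree. For
conservation prioritisation one often needs the opposite view: a per-species
score that apportions the total PD among the leaves, crediting each species
with its share of unique and shared evolutionary history. Functions that do
this are *phylogenetic diversity indices*; the two in common use are the
**Fair Proportion** index (FP, the "Evolutionary Distinctiveness" score used
in EDGE-style rankings) and the **Equal-Splits** index (ES).

`pdspace` implements the general theory behind such indices for rooted trees
with positive branch lengths. An index is a coefficient matrix
`γ(x, e)` giving leaf `x`'s share of edge `e`, subject to

- **allocation**: `γ ≥ 0` and every edge's coefficients sum to 1, so the
  scores `φ(x) = Σ_e γ(x, e) ℓ(e)` always sum to `PD(T, ℓ)`;
- **descent**: `γ(x, e) = 0` unless `x` is descended from `e`;
- **neutrality**: coefficients depend only on the *shape* of the subtree below
  `e`, and are equal at symmetric (corresponding) leaf positions.

FP takes `γ(x, e) = 1 / |c(e)|` (equal shares across the cluster below `e`);
ES takes `γ(x, e) = 1 / Π(e, x)` (splitting evenly at every vertex on the way
down). The package treats these as two points in the convex space of **all**
diversity indices on a tree and provides:

- a validating Newick reader/writer, canonical tree-shape codes, symmetry
  orbits, cluster/path/pendant-subtree/edge-contraction primitives;
- FP, ES and user-supplied coefficient matrices (TSV), with full validation
  of the allocation, descent and neutrality conditions;
- the *consistent* (flow) form of an index: per-vertex ratios of allocation,
  reconstruction of coefficients as path products, a flow-based evaluator,
  and the conversion of any index into a coincident consistent one;
- the geometry of the index space: tree-shape equivalence classes and their
  degrees of freedom, the space's dimension, its corner (extreme) indices,
  Carathéodory bases, barycentric coordinates, per-leaf score bounds, and a
  seeded sampler of random indices;
- the edge-contraction continuity property that singles out FP uniquely, with
  an empirical screening tool;
- example trees (including a 25-species hominoid phylogeny) and a seeded
  random tree generator.

## Worked example: the five-leaf caterpillar

```r
library(pdspace)
tree <- make_fixture("cat5")        # ((((x1,x2)f,x3)g,x4)h,x5), unit lengths
fp <- evaluate_index(fp_matrix(tree), tree)
es <- evaluate_index(es_matrix(tree), tree)
round(rbind(FP = fp, ES = es), 4)
#>        x1     x2     x3   x4 x5
#> FP 2.0833 2.0833 1.5833 1.25  1
#> ES 1.8750 1.8750 1.7500 1.50  1
```

Both rows sum to 8, the tree's total PD; x1 and x2 are symmetric and score
equally; x5, attached directly at the root, gets exactly its pendant length.

The space of *all* diversity indices on this tree has two free equivalence
classes (the vertex over the 3-leaf caterpillar plus x4, and the vertex over
the cherry plus x3), hence dimension 2 and four corner indices:

```r
equivalence_classes(tree)
#> diversity index space: 5 leaves, dimension 2, 4 corner(s), 3 class(es)
#>   h: 1 member(s), out-degree 2, dof 1
#>   g: 1 member(s), out-degree 2, dof 1
#>   f: 1 member(s), out-degree 2, dof 0
corner_scores(corner_indices(tree))
#>       x1  x2 x3 x4 x5
#> [1,] 2.5 2.5  1  1  1     # kappa: both free ratios 1:0
#> [2,] 1.5 1.5  3  1  1     # lambda: 1:0 then 0:1
#> [3,] 2.0 2.0  1  2  1     # mu: 0:1 then 1:0
#> [4,] 1.5 1.5  2  2  1     # nu: both 0:1
```

FP and ES are interior points of this space; in the (kappa, lambda, mu)
corner basis their barycentric coordinates are `(p, q) = (7/24, 1/4)` and
`(9/24, 1/2)`:

```r
corner_coordinates(fp, corner_indices(tree)[1:3])
#>        B1        B2        B3
#> 0.4583333 0.2916667 0.2500000
```

Contracting the interior edge `g` shows why FP suits unresolved trees: its
scores change continuously as `ℓ(g) → 0`, whereas ES jumps:

```r
continuity_defect(es_family(), tree, "g", per_leaf = TRUE)
#>         x1         x2         x3         x4         x5
#> 0.04166667 0.04166667 0.08333333 0.16666667 0.00000000
continuity_defect(fp_family(), tree, "g")
#> [1] 0
```

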