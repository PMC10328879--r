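---
title: "Diversity index spaces on rooted trees: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity index spaces on rooted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A rooted phylogenetic tree `T` on taxa `X` has edges directed away from the
root, every internal vertex of out-degree at least 2, and strictly positive
branch lengths `ℓ` (no ultrametric assumption). Its phylogenetic diversity
`PD(T, ℓ)` is the sum of all branch lengths. A *diversity index* apportions
PD among the leaves through a coefficient matrix `γ(x, e)`:

* `φ(x) = Σ_e γ(x, e) ℓ(e)` with `γ ≥ 0`, so scores are linear in the branch
  lengths and never negative;
* each edge's coefficients sum to 1, which is equivalent to
  `Σ_x φ(x) = PD(T, ℓ)` for every length assignment;
* *descent*: an edge is shared only among the leaves below it;
* *neutrality*: the coefficients of an edge are a function of the tree shape
  of its pendant subtree, equal at leaf positions exchanged by a symmetry.

Fair Proportion (`fp_matrix()`) shares each edge equally over its cluster;
Equal-Splits (`es_matrix()`) halves (splits `1/d`) at each vertex on the way
down. `check_allocation()` and `check_diversity_index()` validate arbitrary
matrices against these conditions and report each violation.

The interesting structure is the set `S(T, ℓ)` of all score vectors of valid
indices. It is convex (coefficient matrices blend entrywise), compact, and
bounded leafwise by `score_bounds()`: every index gives a leaf at least its
pendant length and at most `Σ ℓ(e)/σ_x(e)` along its root path, where
`σ_x(e)` is the size of the leaf's symmetry orbit below `e`.

## Consistency and flow evaluation

An index is *consistent* at a vertex when every ancestral edge is divided
among the vertex's maximal pendant subtrees in one fixed ratio. Consistent
indices can be evaluated by a flow algorithm (`flow_scores()`): each interior
edge's weight is pushed onto its child edges in the vertex's ratio, and a
leaf's score is the final weight of its pendant edge. Total weight is
conserved at every push, so conservation of PD is structural rather than
numerical.

Ratios are stored in a `ratio_scheme`, keyed either by *class signature* (the
multiset of child subtree shape codes — the same entry then serves every
vertex with that signature, which makes the neutrality condition automatic)
or by vertex name. `matrix_to_consistent()` converts any valid index into a
coincident consistent one by summing, at each vertex, the group allocations
of the edges on its root path weighted by their lengths. These per-vertex
ratios are generally *not* equal across vertices that share a signature (the
ancestral edges differ), which is why vertex keys exist and take precedence.
A technical corner: a ratio would be undefined at a vertex receiving no
allocation from any ancestral edge, but for a valid index this cannot happen
— the vertex's own incoming edge always contributes allocations summing to 1
and lengths are positive. The leaf-count-proportional fallback in the code is
defensive only.

## The combinatorial geometry

Internal non-root vertices are grouped by their class signature. A class
whose representative has `g` distinct child shapes carries `g − 1` degrees of
freedom; `space_dimension()` reports the total over classes, the number of
free ratio parameters available to a class-keyed (shape-neutral, consistent)
index. It is 0 exactly on semi-balanced trees — trees whose maximal root
subtrees are each internally shape-homogeneous — where all indices coincide
and FP equals ES; it never exceeds `n − 2`.

Extreme choices — giving a class's entire allocation to one distinct child
shape, split equally within that shape's multiplicity — produce the *corner
indices* (`corner_indices()`), enumerated in a deterministic lexicographic
order: classes by representative preorder position, choices by canonical
shape code, all-first-choices first. On the unit five-leaf caterpillar the
four corners carry score vectors `[2.5, 2.5, 1, 1, 1]`, `[1.5, 1.5, 3, 1, 1]`,
`[2, 2, 1, 2, 1]` and `[1.5, 1.5, 2, 2, 1]`, and `corner_coordinates()`
places FP and ES at `(p, q) = (7/24, 1/4)` and `(9/24, 1/2)` in the basis of
the first three. `caratheodory_basis()` builds `d + 1` corners (the
all-first-choice corner plus one single-class alternative per degree of
freedom); coordinates are solved by QR with an explicit affine-span residual
check and a convexity (non-negative weight) check, both at `1e-9`.

Because no two vertices of one class can be nested, the flow score map is
multilinear in the per-class ratio parameters, so every class-keyed scheme's
score vector is *exactly* the product-weighted convex combination of the
corner score vectors — the form in which the test suite verifies hull
membership.

## A known limitation of the dimension count

`space_dimension()` counts free ratio parameters of class-keyed consistent
indices. It is tempting to read it as the affine dimension of the full convex
space `S(T, ℓ)`, and on trees whose classes are all singletons (the five-leaf
examples shipped as fixtures) the two agree. They do **not** agree in
general: when one equivalence class has members sitting in different
ancestral contexts, the shared ratio multiplies different incoming weights,
and the corner score vectors span more affine directions than the parameter
count. The package's own test suite exhibits this: the tree
`((((x5,x8),x6),x7),((x2,x3),x4),x1,x9)` has two degrees of freedom but
corner affine rank 3, and the hominoid fixture has nine degrees of freedom
but corner affine rank 12. The corner affine rank is always at least the
combinatorial count. Users who need the affine dimension of the realised
score space should compute the rank of `corner_scores()` directly;
`space_dimension()` is the right notion for parametrising, sampling and
enumerating shape-neutral consistent indices, and matches the documented
five-leaf and hominoid counts.

## Continuity and the characterisation of Fair Proportion

For an *index family* (a rule assigning a matrix to every tree), the
continuity defect at an interior edge compares the scores with that edge's
length set to zero — computed exactly via linearity by zeroing the length,
no limits are taken numerically — with the family's scores on the contracted
tree. FP's coefficients depend only on cluster sizes, which contraction
preserves, so its defect is identically zero; this property characterises FP.
`verify_fp_uniqueness()` screens FP, ES and sampled families over random
trees. Note that the defect is a max over leaves: on the unit five-leaf
caterpillar, contracting the edge above the three-leaf subtree gives ES a
defect of 1/12 at the leaf `x3` discussed with that example, while the
overall max is 1/6 (at `x4`, whose vertex context changes out-degree).
Promoting a class-keyed scheme to a family needs a completion rule for
signatures first created by contraction; `scheme_family()` uses the
leaf-count-proportional (FP) ratio and says so in a message.

## Synthetic data and fixtures

`random_tree(n, seed, multifurcation_prob)` grows a binary tree by attaching
leaves one at a time above a uniformly chosen edge, then contracts each
interior non-root edge independently with the given probability; lengths are
unit unless a sampler is supplied. This emulates the combinatorial variety of
rooted tree shapes — including multifurcations — that the theory quantifies
over. It does not emulate evolutionary branch-length processes (no Yule or
coalescent waiting times, no ultrametricity, no rate heterogeneity), so
passing tests certify the combinatorial and algebraic claims, not any
statistical behaviour on empirical phylogenies. Property suites run at
n ≤ 12 with a multifurcation probability of 0.15–0.2: shapes at that size
already exercise every structural case (nested classes, repeated shapes,
multifurcations) while keeping the full suite under a minute.

The named fixtures are the worked trees used throughout: the five-leaf
caterpillar (`cat5`, with its edges `f`, `g`, `h` named), a one-dimensional
five-leaf tree (`fig3`), a non-binary five-leaf tree (`fig4a`), a
semi-balanced five-leaf tree (`fig4b`), a seven-leaf tree with two isomorphic
three-leaf subtrees (`fig2`), and a 25-species hominoid (great ape and
gibbon) phylogeny. The hominoid topology is a transcription chosen to
realise the documented class structure — nine one-degree-of-freedom classes
(one triple of leaf-plus-cherry vertices, one pair of 2,3-vertices, two
distinct five-leaf-subtree classes) and two zero-degree classes — and a test
locks exactly that structure. For `fig2` only the minimal topology forced by
its documented coefficient equalities is encoded, and only those equalities
are tested.

## Numerical conventions

* All arithmetic is double precision. The defining conditions are exact
  rational identities; every comparison (column sums, neutrality equalities,
  consistency proportionality, coordinate residuals) uses an absolute
  tolerance of `1e-9`, far above accumulated round-off at desk scale and the
  convention used for "coinciding" scores as well.
* Canonical order everywhere: children of a vertex are sorted by canonical
  shape code (AHU-style, radix/C locale), ties broken by smallest descendant
  leaf label. Vertex auto-names (`v<k>`), matrix columns, ratio positions
  and corner enumeration all inherit this order, so results are reproducible
  across runs and platforms.
* Edges are addressed by their terminal vertex's name; unlabelled internal
  vertices are auto-named by canonical preorder index at parse time and keep
  their names through contraction and subtree extraction.
* The Newick dialect is strict: one rooted tree, no length on the root, no
  out-degree-1 vertices, duplicate labels rejected, missing lengths default
  to 1 with a warning. Parse errors name the character position.
* Degenerate inputs: the single-vertex tree is a valid one-leaf tree with
  PD 0, an empty coefficient matrix and score vector `[0]`; stars have
  dimension 0; cherries force the 1/2–1/2 split.
* `sample_index()` draws each class's distinct-shape totals from a flat
  Dirichlet (symmetric, concentration 1) on the simplex — the interval
  constraints on per-position ratios are exactly the simplex constraints on
  group totals, so no rejection step is needed — and splits equally within a
  shape group. Seeds are applied locally and restore the caller's RNG state.
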