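# treecarto

Tools for working with the *split space* of unrooted binary phylogenetic
trees and a fast, linear, **cartographic projection** of that space to 2-D
or 3-D — the kind of projection that makes the parsimony landscape of a
tree search visible and, because it is linear and deterministic, usable
*inside* a search rather than only as a post-hoc picture.

## Who this is for

Researchers in phylogenetics who want to

* visualize clouds of candidate topologies (exhaustive sets, rearrangement
  neighborhoods, search traces) colored by parsimony score,
* measure how well a low-dimensional embedding preserves topological
  locality, or
* experiment with search strategies that exploit geometric structure in
  tree space.

## The model

For `n` taxa, every internal branch of an unrooted binary tree (*n*-tree:
all vertices of degree 1 or 3) bipartitions the taxa into a nontrivial
**split**.  Split space is `R^(2^(n-1) - n - 1)`, one 0/1 coordinate per
possible split.  A tree maps to the vector with 1s at its `n - 3` splits,
so **every topology lies on a hypersphere** of squared radius `n - 3`, and
the squared Euclidean distance between two embedded trees equals their
Robinson–Foulds distance (full symmetric-difference convention — twice the
value some tools report).

The cartographic projection takes `k` (default 3) fixed reference vectors
and sends a tree to its `k` inner products.  Because a tree's vector has
only `n - 3` unit entries, the projection is a sum of `n - 3` table rows:
`O(n)` per tree.  The reference vectors are never stored explicitly:
entry `i` of reference vector `j` is `R[h(i) mod d, j]`, where `R` is a
`d x k` matrix (default `d = 65535`) of uniform(−1, 1) draws made
orthogonal by Gram–Schmidt and rescaled to equal magnitude, and `h` is
Bob Jenkins' one-at-a-time hash of the split's canonical byte key.

## Worked example

The five-taxon tree `((1,2),3,(4,5))` has two nontrivial splits, `{1,2}`
and `{4,5}`.  Assign `{1,2}` the reference coordinates `(1.0, 0.9)` and
`{4,5}` the coordinates `(-0.3, 0.6)`; the tree projects to their sum:

```r
library(treecarto)
tm   <- taxon_map(as.character(1:5), sort = FALSE)
tree <- read_newick("((1,2),3,(4,5));", tm)
rvs  <- explicit_reference_set(list(c("1", "2"), c("4", "5")),
                               rbind(c(1.0, 0.9), c(-0.3, 0.6)), tm)
project(tree, rvs)
#> [1] 0.7 1.5
```

With a tiny hash table instead — slot = (sum of the two-taxon side) mod 3,
slot vectors `0 -> (1.0, 0.9)`, `1 -> (-0.9, 0.9)`, `2 -> (-0.8, -0.8)` —
both splits hash to slot 0 and the tree lands at twice that vector:

```r
toy <- build_reference_set(k = 2, d = 3, seed = 1,
                           scheme = hash_scheme("modulo_sum"))
toy$R <- rbind(c(1.0, 0.9), c(-0.9, 0.9), c(-0.8, -0.8))
project(tree, toy)
#> [1] 2.0 1.8
```

A production-scale reference set, and the diagnostics that check what the
construction promises (full rank, near-orthogonality, near-equal
magnitude of the implicitly expanded vectors):

```r
rvs3 <- build_reference_set(k = 3, d = 65535, seed = 42)
round(project(tree, rvs3), 4)
#> [1]  0.0366  1.8106 -0.9034
projection_diagnostics(rvs3, 8)
#> projection_diagnostics: n = 8 (split-space dim 119 )
#>   rank: 3
#>   pairwise angles (deg): 89.1731 86.1409 91.7273
#>   magnitude ratios: 1.000000 0.955009 0.913764
#>   xi: 118.784
```

(The angles tighten toward 90 as split-space dimension grows relative to
the table: under one degree by `n = 16`.)

Other entry points: `enumerate_trees()` (all `(2n-5)!!` topologies),
`rf_distance()` / `rf_matrix()`, `majority_consensus()` + `resolution()`,
`mds_embed()` (stress-majorization MDS baseline), `locality_experiment()`
(neighborhood-consensus comparison of projections), `fitch_score()`,
`tbr_neighborhood()`, `hill_climb()`, `simulate_alignment()`,
`invert_projection()` (point → trees), and a CLI
(`inst/cli/treecarto`, or `treecarto_cli()` in R) with subcommands
`enumerate | project | invert | locality | spectrum | search | simulate`.

## Vignette

`vignettes/treecarto-methods.Rmd` documents the model and its assumptions,
the parameters that matter, what the synthetic data emulate (and do not),
numerical choices, and known limitations.
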