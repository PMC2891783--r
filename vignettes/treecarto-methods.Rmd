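---
title: "Split space, cartographic projections, and how treecarto evaluates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split space, cartographic projections, and how treecarto evaluates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecarto)
```

## The space and the projection

treecarto works with fully resolved unrooted topologies on `n` labeled
taxa (*n*-trees: every vertex has degree 1 or 3).  Each of the `n - 3`
internal branches bipartitions the taxa into a nontrivial *split*; the
tree is identified with its split set.  Split space assigns one 0/1
coordinate to each of the `2^(n-1) - n - 1` possible splits, so a tree
becomes a sparse vector with exactly `n - 3` unit entries.  Two
consequences drive everything else:

* **Hypersphere**: every topology has squared norm `n - 3`, so the whole
  space of topologies lies on a sphere about the origin — the precondition
  for map-style (cartographic) sphere-to-plane projection.
* **Distance**: the squared Euclidean distance between two embedded trees
  is exactly their Robinson–Foulds distance in the full
  symmetric-difference convention.  We keep that convention (not the
  halved one) precisely because of this identity; `rf_distance()`'s help
  page flags it.

The cartographic projection picks `k` reference vectors and maps a tree to
its `k` inner products with them.  It is linear, deterministic per taxon
map, and `O(n)` per tree once reference entries are table lookups.

### Why a hash table

Split space has dimension `2^(n-1) - n - 1`; explicit reference vectors
die of memory long before interesting `n`.  Instead we store `k`
*representative* vectors of fixed length `d` and read entry `i` of
reference vector `j` as `R[h(i) mod d, j]`.  All structural quality of the
projection then rides on two things this package makes checkable rather
than assumed:

* the representatives' construction — uniform(−1, 1) draws, classical
  Gram–Schmidt, rescaling of every column to the first column's magnitude
  (true unit normalization would underflow: spreading norm 1 over millions
  of coordinates makes entries denormal, so equal magnitude is enforced
  instead); and
* the hash — Bob Jenkins' one-at-a-time over a canonical byte key
  (`n` then the sorted 0-based canonical-side indices, each 4-byte
  big-endian; injective per taxon map and platform-stable).

`projection_diagnostics()` expands the *true* reference vectors for small
`n` and reports rank, pairwise angles, magnitudes, per-slot occupancy
`f_i`, and the evenness statistic `xi = sum_i (f_i - d'/d)^2`.  The
verbal definition of this statistic fixes it only up to normalization, so
the raw `f_i` are returned too and any alternative normalization can be
recomputed from them.  Empirically (and tested): rank is `k` across
seeds; `xi = 0` forces magnitude ratios of exactly 1; and angle deviation
from 90° shrinks as `d'/d` grows — a few degrees while `d' << d`
(`n = 12`, `d' = 2035`, `d = 65535`), under one degree by `n = 16`.  We
deliberately do not assert any closed-form angle bound: the one printed in
the source material is not re-derivable from its text.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `k` | 3 | output dimensions; 3-D preserves more structure than 2-D and is still displayable |
| `d` | 65535 | representative length; memory/quality dial, independent of `n` |
| `seed` | — | drives the representative draws; everything is bit-reproducible from it |
| hash | `jenkins_oaat` | any good byte hash works; `modulo_sum` ships as the didactic toy |
| `tol` (inversion) | 1e-9 | acceptance radius around a target point |
| `p_change` (simulator) | — | per-branch change probability, `[0, 0.75]` |

Splits are summed in increasing canonical-mask order when projecting, so
the hash path agrees *bit for bit* with a dense matrix product (the dense
summation meets the same nonzero terms in the same order, and adding
exact zeros is an IEEE identity).  That equality — not an approximate
one — is what the oracle-equivalence test asserts over all 945
seven-taxon trees and five seeds.

## The locality experiment

To show a projection preserves topological locality we embed the complete
set of `n = 7` topologies (945 of them), and for every tree take the
majority-rule consensus of its `m` nearest neighbors (itself included;
ties broken by ascending tree index) for `m = 0..25`.  Consensus
*resolution* — the fraction of the `n - 3` possible splits that are
present — is 1 when the neighborhood agrees on a full topology and 0 when
it agrees on nothing; at `m = 0` it is 1 by construction, and over the
whole 15-tree space at `n = 5` it is 0 (every split occurs in 3 of 15
trees).  Each of the default 100 replicates (10 in the test suite, for
budget) redraws each method's random element: a fresh reference set for
the cartographic projection, a fresh random initialization for MDS.

The baseline is metric MDS of the Robinson–Foulds matrix by stress
majorization (SMACOF/Guttman transform), in 2-D and 3-D, written
in-package so its stress sequence is recorded and its monotone
non-increase is a tested contract rather than a belief about a library.

Two design choices differ from the obvious alternatives:

* **Like-for-like pools.**  If the topology count exceeds the `subsample`
  cap (relevant from `n = 8`; `10,395^2` distance matrices are where
  MDS stops being desk-scale), one seeded subsample per replicate is used
  for *all* methods, not just for MDS.  Subsampling only the baseline
  would give the denser cartographic cloud systematically closer
  neighbors and bias its consensus upward.
* **Neighborhoods in each method's own embedded metric**, Euclidean in
  both cases — the comparison is about what each embedding's geometry
  preserves.

The tested claim is comparative and statistical: over 10 replicates at
`n = 7`, the cartographic projection's mean average resolution is not
significantly below either MDS baseline at any `m` in 1..25 (one-sided
paired t at alpha = 0.01).  In every run to date it is far above them.

## Search machinery

Parsimony is Fitch's small-parsimony count over site patterns
(pattern-compressed with weights), computed on a copy rooted at the
internal vertex adjacent to taxon 1 — the score is rooting-invariant,
which the suite checks, alongside a brute-force oracle over all internal
labelings at small `n` and phangorn's independent implementation.  Gaps
and `?`/`N` map to the full nucleotide set; IUPAC codes to their sets.

TBR neighborhoods are enumerated at the topology level: cut each branch,
suppress degree-2 vertices, rejoin every edge pair across the components,
deduplicate by canonical split set.  A definitional oracle (a shared
edge-removal bipartition whose induced subtrees match on both sides)
validates the enumeration exhaustively at `n = 5`.  One empirical note: at
`n = 5` a single TBR move always preserves either a cherry or a leaf's
quartet context, so exactly 12 of the 14 other topologies are one move
away — full coverage needs two moves.  `hill_climb()` is plain steepest
descent with ties broken by lowest canonical split-set encoding
(deterministic), recording every `sampling_period`-th evaluated
rearrangement (default 100) so rejected trees can be projected alongside
the accepted path.

### Inverting the projection

Linearity makes a target point correspond to an affine subspace of split
space.  Up to `exhaustive_max = 9` taxa (135,135 topologies) inversion
enumerates and filters — guaranteed complete.  Beyond that a beam search
grows compatible split sets in canonical order, scoring partial sums
against the proportionally scaled target.  Honesty requires saying this
regime is weak: three coordinates constrain a prefix of a split set very
little, and in experiments the beam missed an `n = 8` source tree even at
width 1024 (hence the extended exhaustive regime).  The beam is kept for
large `n` as a sound-but-incomplete tool: anything it returns projects
within `tol`.

## The synthetic generator

`simulate_alignment()` evolves i.i.d. sites root-to-tip with a single
per-branch change probability and uniform choice among the three other
nucleotides.  It emulates exactly what the evaluation needs — alignments
whose parsimony scores vary coherently over topologies, with a known
generating tree — and none of what real data have: no rate heterogeneity,
no transition/transversion bias, no branch-length variation, no indels,
no alignment error.  A green parameter-recovery test (500 sites,
`p_change = 0.05`, `n = 7`: exhaustive search finds the generating
topology in at least 9 of 10 seeds) therefore establishes that the
scoring and search machinery are wired correctly, not that any real data
set is this easy.  Defaults follow that stated regime; they were chosen
once and are not tuned.

## Numerical and degenerate-input choices

* Canonical split side: the side *not* containing taxon 1, as a bitmask
  (so n is capped at 30; dense vectors and diagnostics at `n = 16`).
* Taxon order: lexicographic unless an explicit `taxon_map` is given;
  all cross-tree operations demand identical maps, because split identity
  depends on indexing.  Relabeling taxa moves projected points.
* `resolution()` at `n = 3`: the denominator `n - 3` vanishes; defined as
  1, since the 3-taxon star *is* the fully resolved topology.
* Rooted Newick input is unrooted by suppressing the degree-2 root; any
  other multifurcation is an error.  Branch lengths are parsed, ignored.
* The modulo-sum toy hash sums the *smaller* side's 1-based taxon
  numbers (ties toward the canonical side): that is the convention under
  which the printed worked example's slot assignments reproduce.
* SMACOF handles coincident points by zeroing the ratio term; stress is
  recorded per iteration and must never increase.

## Known limitations

* Topologies only: no branch lengths, no geodesic (orthant) geometry, no
  likelihood scoring.
* The locality experiment is exhaustive-enumeration-bound (`n <= 8`).
* Beam inversion beyond `n = 9` is heuristic (above).
* The projection is taxon-map-specific; coordinates are not comparable
  across different taxon sets or orderings.
* `hill_climb()` implements steepest descent only — no ratchet, no
  simulated annealing, no randomized tie-breaking.
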