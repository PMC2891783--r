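# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (masks, indexers, colSums order) wherever they
# check one.

tm5 <- taxon_map(as.character(1:5), sort = FALSE)

# recursive topology counter: f(3) = 1, f(n) = (2n - 5) * f(n - 1)
count_topologies_oracle <- function(n) {
  if (n == 3) return(1)
  (2 * n - 5) * count_topologies_oracle(n - 1)
}

# split compatibility on explicit label sets: compatible iff one of the four
# side intersections is empty
compatible_oracle <- function(side_a, side_b, labels) {
  ca <- setdiff(labels, side_a)
  cb <- setdiff(labels, side_b)
  any(c(length(intersect(side_a, side_b)) == 0,
        length(intersect(side_a, cb)) == 0,
        length(intersect(ca, side_b)) == 0,
        length(intersect(ca, cb)) == 0))
}

# splits of a tree as sorted label-set strings (via the package's masks only
# for decoding, but compared against hand-listed expectations in tests)
split_sides <- function(t) {
  n <- t$taxa$n
  sort(vapply(tree_splits(t)$masks, function(m) {
    side <- t$taxa$labels[treecarto:::mask_to_side(m, n)]
    paste(sort(side), collapse = "|")
  }, ""))
}

# brute-force Fitch for one site: minimize changes over all assignments of
# single states to internal vertices
fitch_site_oracle <- function(t, tip_states) {
  n <- t$taxa$n
  n_int <- n - 2L
  best <- Inf
  grid <- do.call(expand.grid, rep(list(1:4), n_int))
  for (g in seq_len(nrow(grid))) {
    assign_states <- c(tip_states, as.integer(grid[g, ]))
    changes <- sum(assign_states[t$edge[, 1]] != assign_states[t$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# brute-force m-nearest neighborhood: full sort with index tie-break
knn_oracle <- function(points, focal, m) {
  d <- sqrt(rowSums((points - matrix(points[focal, ], nrow(points),
                                     ncol(points), byrow = TRUE))^2))
  ord <- order(d, seq_len(nrow(points)))
  ord <- ord[ord != focal]
  c(focal, ord[seq_len(m)])
}

# dense-matrix projection oracle: expand the k reference vectors over the
# explicit split space and take the matrix product with the 0/1 embedding,
# accumulating in index order
dense_project_oracle <- function(t, rvs, idx) {
  E <- reference_entries(rvs, idx$masks, idx$n)
  v <- split_vector(t, idx, dense = TRUE)
  colSums(v * E)
}

# the toy scheme printed in the worked example: modulo-3 hash with slot
# vectors 0 -> (1.0, 0.9), 1 -> (-0.9, 0.9), 2 -> (-0.8, -0.8)
toy_modulo3_set <- function() {
  rvs <- build_reference_set(k = 2, d = 3, seed = 1,
                             scheme = hash_scheme("modulo_sum"))
  rvs$R <- rbind(c(1.0, 0.9), c(-0.9, 0.9), c(-0.8, -0.8))
  rvs
}

ntree_to_phangorn <- function(t) {
  ape::unroot(ape::read.tree(text = write_newick(t)))
}

# definitional TBR-adjacency oracle: one move separates a and b iff some
# edge-removal bipartition (trivial or not) exists in both trees and the
# induced subtrees on each side are topologically equal (ape restrictions)
tbr_adjacent_oracle <- function(a, b) {
  labs <- a$taxa$labels
  n <- a$taxa$n
  pa <- ape::unroot(ape::read.tree(text = write_newick(a)))
  pb <- ape::unroot(ape::read.tree(text = write_newick(b)))
  sides <- function(t) {
    nt <- lapply(tree_splits(t)$masks,
                 function(m) labs[treecarto:::mask_to_side(m, n)])
    c(as.list(labs), nt)
  }
  restr_eq <- function(tips) {
    if (length(tips) <= 3) return(TRUE)
    ape::dist.topo(ape::unroot(ape::keep.tip(pa, tips)),
                   ape::unroot(ape::keep.tip(pb, tips))) == 0
  }
  sb <- sides(b)
  for (A in sides(a)) {
    shared <- any(vapply(sb, function(x) {
      setequal(x, A) || setequal(x, setdiff(labs, A))
    }, TRUE))
    if (!shared) next
    if (restr_eq(A) && restr_eq(setdiff(labs, A))) return(TRUE)
  }
  FALSE
}
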