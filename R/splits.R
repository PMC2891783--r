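## Splits (nontrivial bipartitions) and their canonical bitmask encoding.
##
## A split is stored as a 32-bit integer bitmask over taxon positions: bit
## (i - 1) is set iff taxon i lies on the canonical side, defined as the side
## NOT containing taxon 1 (so bit 0 is always clear).  Masks are unique,
## cheap to hash and order, and valid for n <= 30.

mask_bit <- function(i) bitwShiftL(1L, i - 1L)

side_to_mask <- function(side) {
  m <- 0L
  for (i in side) m <- bitwOr(m, mask_bit(i))
  m
}

mask_to_side <- function(mask, n) {
  which(bitwAnd(mask, mask_bit(seq_len(n))) != 0L)
}

popcount <- function(mask) {
  k <- 0L
  while (mask != 0L) {
    mask <- bitwAnd(mask, mask - 1L)
    k <- k + 1L
  }
  k
}

full_mask <- function(n) {
  if (n >= 31L) stop("split masks support at most 30 taxa")
  bitwShiftL(1L, n) - 1L
}

#' Canonicalize a split given by one of its sides
#'
#' @param side integer vector of 1-based taxon positions on either side of
#'   the bipartition.
#' @param n number of taxa.
#' @return the canonical integer bitmask (the side not containing taxon 1).
#' @export
canonical_split <- function(side, n) {
  side <- unique(as.integer(side))
  if (any(side < 1L) || any(side > n)) stop("taxon position out of range")
  m <- side_to_mask(side)
  if (bitwAnd(m, 1L) != 0L) m <- bitwXor(full_mask(n), m)
  sz <- popcount(m)
  if (sz < 2L || sz > n - 2L) {
    stop("trivial split: each side must contain at least two taxa")
  }
  m
}

# Two splits are compatible iff one of the four side intersections is empty.
splits_compatible <- function(a, b, n) {
  fm <- full_mask(n)
  ac <- bitwXor(fm, a)
  bc <- bitwXor(fm, b)
  bitwAnd(a, b) == 0L || bitwAnd(a, bc) == 0L ||
    bitwAnd(ac, b) == 0L || bitwAnd(ac, bc) == 0L
}

new_split_set <- function(masks, taxa) {
  structure(list(masks = sort(as.integer(masks)), taxa = taxa),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  n <- x$taxa$n
  cat("split_set:", length(x$masks), "nontrivial splits on", n, "taxa\n")
  for (m in x$masks) {
    side <- x$taxa$labels[mask_to_side(m, n)]
    cat("  {", paste(side, collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

#' Extract the nontrivial splits of a tree
#'
#' Every internal branch of an n-tree bipartitions the taxa; the n - 3
#' nontrivial splits, in canonical encoding, characterize the topology.
#'
#' @param t an [ntree()].
#' @return a `split_set`: canonical split masks (sorted ascending) plus the
#'   taxon map.
#' @export
tree_splits <- function(t) {
  n <- t$taxa$n
  r <- rooted_children(t)
  ord <- r$order
  sub <- integer(2L * n - 2L)
  for (v in rev(ord)) {
    if (v <= n) {
      sub[v] <- mask_bit(v)
    } else {
      m <- 0L
      for (w in r$children[[v]]) m <- bitwOr(m, sub[w])
      sub[v] <- m
    }
  }
  # each non-root vertex's subtree is the side of its parent edge away from
  # taxon 1, hence already canonical; keep the nontrivial ones
  masks <- integer(0)
  for (v in ord[-1L]) {
    sz <- popcount(sub[v])
    if (sz >= 2L && sz <= n - 2L) masks <- c(masks, sub[v])
  }
  new_split_set(masks, t$taxa)
}

#' Reconstruct the tree from a compatible split set
#'
#' Builds the unique unrooted binary topology whose internal branches induce
#' exactly the given n - 3 pairwise-compatible splits, working from the
#' smallest canonical sides outward (the classic perfect-phylogeny
#' construction).
#'
#' @param s a `split_set` (from [tree_splits()] or [make_split_set()]).
#' @param taxa optional taxon map overriding `s$taxa`.
#' @return an [ntree()] with `tree_splits(result)` equal to `s`.
#' @export
splits_to_tree <- function(s, taxa = NULL) {
  if (is.null(taxa)) taxa <- s$taxa
  n <- taxa$n
  masks <- s$masks
  if (length(masks) != n - 3L) {
    stop("expected ", n - 3L, " splits for ", n, " taxa, got ", length(masks))
  }
  if (length(masks) > 1L) {
    for (i in seq_along(masks)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!splits_compatible(masks[i], masks[j], n)) {
          stop("incompatible split pair: {",
               paste(taxa$labels[mask_to_side(masks[i], n)], collapse = ","),
               "} vs {",
               paste(taxa$labels[mask_to_side(masks[j], n)], collapse = ","),
               "}")
        }
      }
    }
  }
  sizes <- vapply(masks, popcount, 0L)
  masks <- masks[order(sizes, masks)]
  # available clades: vertex id + leaf-set mask; taxon 1 is kept apart and
  # joined at the final internal vertex
  avail_v <- 2:n
  avail_m <- vapply(2:n, mask_bit, 0L)
  edges <- matrix(0L, nrow = 2L * n - 3L, ncol = 2L)
  ne <- 0L
  next_internal <- n + 1L
  for (m in masks) {
    inside <- bitwAnd(avail_m, m) == avail_m
    cover <- 0L
    for (x in avail_m[inside]) cover <- bitwOr(cover, x)
    if (cover != m || sum(inside) != 2L) {
      stop("split set is not tree-compatible at split {",
           paste(taxa$labels[mask_to_side(m, n)], collapse = ","), "}")
    }
    v <- next_internal
    next_internal <- next_internal + 1L
    for (w in avail_v[inside]) {
      ne <- ne + 1L
      edges[ne, ] <- c(v, w)
    }
    avail_v <- c(avail_v[!inside], v)
    avail_m <- c(avail_m[!inside], m)
  }
  if (length(avail_v) != 2L) stop("split set is not tree-compatible")
  root <- next_internal
  for (w in c(1L, avail_v)) {
    ne <- ne + 1L
    edges[ne, ] <- c(root, w)
  }
  ntree(edges, taxa)
}

#' Construct a split set from sides given as taxon labels
#'
#' @param sides list of character vectors; each vector names the taxa on one
#'   side of a split.
#' @param taxa a [taxon_map()].
#' @return a `split_set`.
#' @examples
#' tm <- taxon_map(as.character(1:5))
#' make_split_set(list(c("1", "2"), c("4", "5")), tm)
#' @export
make_split_set <- function(sides, taxa) {
  masks <- vapply(sides, function(s) canonical_split(taxon_index(taxa, s),
                                                     taxa$n), 0L)
  if (anyDuplicated(masks)) stop("duplicate splits")
  new_split_set(masks, taxa)
}

#' Topological equality of two trees
#'
#' Trees are equal iff they share a taxon map and have identical canonical
#' split sets.
#'
#' @param a,b [ntree()] objects.
#' @return logical.
#' @export
topo_equal <- function(a, b) {
  same_taxa(a$taxa, b$taxa) &&
    identical(tree_splits(a)$masks, tree_splits(b)$masks)
}

# deterministic string key for a topology (used for dedup / tie-breaking)
topo_key <- function(masks) paste(masks, collapse = ".")
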