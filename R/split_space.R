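#' Split-space indexer
#'
#' Split space for n taxa is the Euclidean space with one 0/1 coordinate per
#' possible nontrivial bipartition; its dimension is 2^(n-1) - n - 1.  The
#' indexer realizes the bijection between canonical split masks and dimension
#' indices 1..dim (masks ranked in increasing integer order).  Explicit
#' indexers are only instantiated for n <= 16 (they are the dense oracle used
#' to validate the hash-table projection).
#'
#' @param n taxon count, 4 <= n <= 16.
#' @return object of class `split_indexer` with fields `n`, `dim`, `masks`.
#' @examples
#' split_indexer(5)$dim  # 10
#' @export
split_indexer <- function(n) {
  n <- as.integer(n)
  if (n < 4L || n > 16L) stop("explicit split indexers require 4 <= n <= 16")
  # canonical masks: subsets of taxa {2..n} (bit 0 clear) with 2..n-2 members
  half <- 0:(2^(n - 1L) - 1L)
  masks <- as.integer(half * 2L)
  sizes <- vapply(masks, popcount, 0L)
  masks <- masks[sizes >= 2L & sizes <= n - 2L]
  masks <- sort(masks)
  dim <- 2^(n - 1L) - n - 1L
  stopifnot(length(masks) == dim)
  structure(list(n = n, dim = as.integer(dim), masks = masks),
            class = "split_indexer")
}

#' @export
print.split_indexer <- function(x, ...) {
  cat("split_indexer: n =", x$n, ", dimension", x$dim, "\n")
  invisible(x)
}

#' Index of a split in split space
#'
#' @param mask canonical split mask(s) (see [canonical_split()]).
#' @param idx a [split_indexer()].
#' @return integer index (1-based) into the `idx$dim` dimensions.
#' @export
split_index <- function(mask, idx) {
  i <- match(as.integer(mask), idx$masks)
  if (anyNA(i)) stop("mask is not a valid nontrivial split for n = ", idx$n)
  i
}

#' Split at a given index
#'
#' @param i index in 1..dim.
#' @param idx a [split_indexer()].
#' @return the canonical split mask.
#' @export
index_to_split <- function(i, idx) {
  if (any(i < 1L | i > idx$dim)) stop("split index out of range")
  idx$masks[i]
}

#' Embed a tree in split space
#'
#' The image of an n-tree is the 0/1 vector with a 1 in each of the n - 3
#' dimensions corresponding to its nontrivial splits.  All n-trees therefore
#' lie on a hypersphere of squared radius n - 3 about the origin.
#'
#' @param t an [ntree()].
#' @param idx a [split_indexer()] for `t`'s taxon count; built on the fly if
#'   missing.
#' @param dense if `TRUE`, return the full numeric vector of length
#'   `idx$dim`; otherwise a sparse representation.
#' @return with `dense = FALSE`, an object of class `split_vector` holding
#'   the sorted 1-indices (`ones`), `n` and `dim`; with `dense = TRUE` a
#'   numeric vector.
#' @export
split_vector <- function(t, idx = NULL, dense = FALSE) {
  if (is.null(idx)) idx <- split_indexer(t$taxa$n)
  if (idx$n != t$taxa$n) stop("indexer is for a different taxon count")
  ones <- sort(split_index(tree_splits(t)$masks, idx))
  if (dense) {
    v <- numeric(idx$dim)
    v[ones] <- 1
    return(v)
  }
  structure(list(ones = ones, n = idx$n, dim = idx$dim),
            class = "split_vector")
}

#' Robinson-Foulds distance
#'
#' The number of splits not shared by the two topologies (symmetric
#' difference of their nontrivial split sets).  Note this is the full
#' symmetric-difference count, not halved or normalized: it equals the
#' squared Euclidean distance between the trees' split-space embeddings,
#' which is the convention the projection geometry relies on.  Many tools
#' report half this value.
#'
#' @param a,b [ntree()] objects over the same taxon map.
#' @return a nonnegative integer; 0 iff the topologies are equal.
#' @export
rf_distance <- function(a, b) {
  stop_unless_same_taxa(a$taxa, b$taxa)
  ma <- tree_splits(a)$masks
  mb <- tree_splits(b)$masks
  length(setdiff(ma, mb)) + length(setdiff(mb, ma))
}

#' Pairwise Robinson-Foulds distance matrix
#'
#' Vectorized over a list of trees via the split-membership incidence matrix.
#'
#' @param trees list of [ntree()] sharing one taxon map.
#' @param idx optional [split_indexer()]; built on the fly for n <= 16.  For
#'   larger n the masks are ranked ad hoc.
#' @return symmetric integer matrix of symmetric-difference counts.
#' @export
rf_matrix <- function(trees, idx = NULL) {
  stopifnot(length(trees) >= 1L)
  taxa <- trees[[1L]]$taxa
  for (t in trees[-1L]) stop_unless_same_taxa(taxa, t$taxa)
  n <- taxa$n
  split_lists <- lapply(trees, function(t) tree_splits(t)$masks)
  all_masks <- sort(unique(unlist(split_lists)))
  m <- matrix(0, nrow = length(trees), ncol = length(all_masks))
  for (i in seq_along(trees)) {
    m[i, match(split_lists[[i]], all_masks)] <- 1
  }
  shared <- tcrossprod(m)
  d <- matrix(n - 3L, length(trees), length(trees)) * 2 - 2 * shared
  storage.mode(d) <- "integer"
  d
}
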