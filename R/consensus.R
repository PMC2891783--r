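#' Majority-rule consensus of a set of trees
#'
#' The consensus contains exactly the splits present in strictly more than
#' half of the input trees.  Majority splits are automatically pairwise
#' compatible, so the result is always a (possibly unresolved) tree.
#'
#' @param trees non-empty list of [ntree()] sharing one taxon map.
#' @return an object of class `consensus_tree` with fields `taxa` and `masks`.
#' @export
majority_consensus <- function(trees) {
  if (length(trees) == 0L) stop("empty tree list")
  taxa <- trees[[1L]]$taxa
  for (t in trees[-1L]) stop_unless_same_taxa(taxa, t$taxa)
  all_masks <- unlist(lapply(trees, function(t) tree_splits(t)$masks))
  counts <- table(all_masks)
  keep <- as.integer(names(counts)[counts > length(trees) / 2])
  structure(list(taxa = taxa, masks = sort(keep), n_input = length(trees)),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("majority-rule consensus of", x$n_input, "trees:",
      length(x$masks), "of", x$taxa$n - 3L, "splits (resolution",
      format(resolution(x), digits = 4), ")\n")
  invisible(x)
}

#' Resolution of a consensus tree
#'
#' The fraction of the n - 3 possible internal splits that are present:
#' 1 for a fully resolved tree, 0 for a star.  For n = 3 (where n - 3 = 0)
#' the value is defined as 1, since the 3-taxon star is the fully resolved
#' topology.
#'
#' @param ct a `consensus_tree` (or any object with `masks` and `taxa`).
#' @return a number in `[0, 1]`.
#' @export
resolution <- function(ct) {
  n <- ct$taxa$n
  if (n == 3L) return(1)
  length(ct$masks) / (n - 3L)
}
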