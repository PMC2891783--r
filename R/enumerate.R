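#' Enumerate all unrooted binary topologies
#'
#' Generates every unrooted binary tree on the given taxa exactly once, in a
#' deterministic leaf-insertion order: taxon k is attached to each branch of
#' each (k-1)-taxon tree, branches visited in edge-matrix row order.  The
#' number of topologies is the double factorial (2n-5)!!.
#'
#' @param taxa a [taxon_map()], or an integer n (labels then default to
#'   `"1" .. "n"` in numeric order).
#' @param FUN optional callback applied to each tree in enumeration order; if
#'   supplied, its results are discarded and the count is returned invisibly
#'   (constant memory).  Otherwise all trees are returned as a list.
#' @return list of [ntree()] (or invisible count when `FUN` is given).
#' @examples
#' length(enumerate_trees(5))  # 15
#' @export
enumerate_trees <- function(taxa, FUN = NULL) {
  taxa <- as_taxa(taxa)
  n <- taxa$n
  count <- 0L
  emit <- function(edge) {
    count <<- count + 1L
    t <- structure(list(edge = edge, taxa = taxa), class = "ntree")
    if (is.null(FUN)) out[[count]] <<- t else FUN(t)
    invisible(NULL)
  }
  if (is.null(FUN)) out <- vector("list", num_topologies(n))
  base <- matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2L, byrow = TRUE)
  grow <- function(edge, k) {
    if (k > n) {
      emit(edge)
      return(invisible(NULL))
    }
    # relabel internals (ids > k-1) up by one to make room for tip k
    shifted <- edge
    shifted[shifted >= k] <- shifted[shifted >= k] + 1L
    new_internal <- 2L * k - 2L
    for (e in seq_len(nrow(shifted))) {
      ne <- shifted
      a <- ne[e, 1L]
      b <- ne[e, 2L]
      ne[e, ] <- c(a, new_internal)
      ne <- rbind(ne, c(new_internal, b), c(new_internal, k))
      grow(ne, k + 1L)
    }
    invisible(NULL)
  }
  grow(base, 4L)
  if (is.null(FUN)) out else invisible(count)
}

as_taxa <- function(taxa) {
  if (inherits(taxa, "taxon_map")) return(taxa)
  n <- as.integer(taxa)
  taxon_map(as.character(seq_len(n)), sort = FALSE)
}

#' Number of unrooted binary topologies, (2n-5)!!
#'
#' @param n taxon count, n >= 3.
#' @return a double (exact for all supported n).
#' @export
num_topologies <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be at least 3")
  if (n == 3L) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}

#' Random unrooted binary topology
#'
#' Uniform over topologies, by sequential random leaf insertion (taxon k is
#' attached to a branch drawn uniformly from the 2k-5 branches of the current
#' tree).  Uses R's global RNG stream; call `set.seed()` for reproducibility.
#'
#' @param taxa a [taxon_map()] or an integer n.
#' @return an [ntree()].
#' @export
random_ntree <- function(taxa) {
  taxa <- as_taxa(taxa)
  n <- taxa$n
  edge <- matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2L, byrow = TRUE)
  if (n > 3L) {
    for (k in 4:n) {
      edge[edge >= k] <- edge[edge >= k] + 1L
      e <- sample.int(nrow(edge), 1L)
      new_internal <- 2L * k - 2L
      b <- edge[e, 2L]
      edge[e, 2L] <- new_internal
      edge <- rbind(edge, c(new_internal, b), c(new_internal, k))
    }
  }
  ntree(edge, taxa)
}
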