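#' Cartographic projection of a tree
#'
#' The linear map sending a tree to the k inner products of its split-space
#' vector with the k reference vectors.  Because the vector has exactly n - 3
#' unit entries, the inner products reduce to summing the k per-split table
#' entries over the tree's nontrivial splits: O(n) per tree.  Splits are
#' summed in increasing canonical-mask order, which matches the dense
#' matrix-product order, so the hash path and the dense oracle agree bit for
#' bit.
#'
#' @param t an [ntree()].
#' @param rvs a [build_reference_set()] or [explicit_reference_set()].
#' @return numeric vector of k coordinates.
#' @examples
#' tm <- taxon_map(as.character(1:5), sort = FALSE)
#' rvs <- explicit_reference_set(list(c("1", "2"), c("4", "5")),
#'                               rbind(c(1.0, 0.9), c(-0.3, 0.6)), tm)
#' project(read_newick("((1,2),3,(4,5));", tm), rvs)  # 0.7 1.5
#' @export
project <- function(t, rvs) {
  masks <- tree_splits(t)$masks  # already sorted ascending
  if (length(masks) == 0L) return(numeric(rvs$k))
  e <- reference_entries(rvs, masks, t$taxa$n)
  .colSums(e, nrow(e), ncol(e))
}

#' Project a list of trees
#'
#' Order-preserving batch version of [project()].  Entries are computed once
#' per distinct split, so projecting a large cloud over a small taxon set is
#' fast.
#'
#' @param trees list of [ntree()] sharing one taxon map.
#' @param rvs reference set.
#' @param scores optional numeric vector of per-tree scores to carry along.
#' @param ids optional identifiers (default `seq_along(trees)`).
#' @return a data.frame with columns `tree_id`, `newick`, the k coordinates
#'   (`x`, `y`, `z`, ... up to k), and optionally `score`.
#' @export
project_batch <- function(trees, rvs, scores = NULL, ids = NULL) {
  k <- rvs$k
  coord_names <- c("x", "y", "z", paste0("c", seq_len(max(0L, k - 3L)) + 3L))[seq_len(k)]
  if (length(trees) == 0L) {
    out <- as.data.frame(c(list(tree_id = integer(0), newick = character(0)),
                           stats::setNames(rep(list(numeric(0)), k),
                                           coord_names)))
    if (!is.null(scores)) out$score <- numeric(0)
    return(out)
  }
  taxa <- trees[[1L]]$taxa
  for (t in trees[-1L]) stop_unless_same_taxa(taxa, t$taxa)
  split_lists <- lapply(trees, function(t) tree_splits(t)$masks)
  uniq <- sort(unique(unlist(split_lists)))
  e <- reference_entries(rvs, uniq, taxa$n)
  coords <- t(vapply(split_lists, function(m) {
    if (length(m) == 0L) return(numeric(k))
    rows <- e[match(m, uniq), , drop = FALSE]
    .colSums(rows, nrow(rows), ncol(rows))
  }, numeric(k)))
  if (is.null(ids)) ids <- seq_along(trees)
  out <- data.frame(tree_id = ids,
                    newick = vapply(trees, write_newick, ""),
                    stringsAsFactors = FALSE)
  colnames(coords) <- coord_names
  out <- cbind(out, as.data.frame(coords))
  if (!is.null(scores)) out$score <- scores
  out
}

#' Empirical diagnostics for a hash-backed reference set
#'
#' Expands the k true reference vectors over the explicit split space of a
#' small taxon set and reports the properties the construction aims for:
#' linear independence (rank k), near-orthogonality (pairwise angles close
#' to 90 degrees), near-equal magnitudes, plus the hash-occupancy counts
#' f_i (how many split-space dimensions land in each table slot) and the
#' evenness statistic xi = sum_i (f_i - d'/d)^2, which is 0 exactly when the
#' hash spreads the d' dimensions perfectly evenly over the d slots.
#'
#' @param rvs a [build_reference_set()].
#' @param n taxon count, 4..16 (the split space is expanded explicitly).
#' @return object of class `projection_diagnostics`: `expanded` (d' x k
#'   matrix), `rank`, `pairwise_angles` (degrees, upper-triangle order),
#'   `magnitudes`, `magnitude_ratios` (relative to the first vector), `f`,
#'   `xi`, `n`, `dim`.
#' @export
projection_diagnostics <- function(rvs, n) {
  idx <- split_indexer(n)
  slots <- rvs$scheme$fun(idx$masks, n, rvs$d)
  E <- rvs$R[slots + 1L, , drop = FALSE]
  k <- rvs$k
  mags <- sqrt(.colSums(E^2, nrow(E), k))
  angles <- c()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cosang <- sum(E[, i] * E[, j]) / (mags[i] * mags[j])
      angles <- c(angles, acos(max(-1, min(1, cosang))) * 180 / pi)
    }
  }
  f <- tabulate(slots + 1L, nbins = rvs$d)
  structure(list(expanded = E,
                 rank = qr(E)$rank,
                 pairwise_angles = angles,
                 magnitudes = mags,
                 magnitude_ratios = mags / mags[1L],
                 f = f,
                 xi = sum((f - idx$dim / rvs$d)^2),
                 n = n, dim = idx$dim),
            class = "projection_diagnostics")
}

#' @export
print.projection_diagnostics <- function(x, ...) {
  cat("projection_diagnostics: n =", x$n, "(split-space dim", x$dim, ")\n")
  cat("  rank:", x$rank, "\n")
  cat("  pairwise angles (deg):",
      paste(format(x$pairwise_angles, digits = 6), collapse = " "), "\n")
  cat("  magnitude ratios:",
      paste(format(x$magnitude_ratios, digits = 6), collapse = " "), "\n")
  cat("  xi:", format(x$xi, digits = 6), "\n")
  invisible(x)
}

#' Invert a projected point back to trees
#'
#' Because the projection is linear, a point in the visualization corresponds
#' to an affine subspace of split space; this searches for n-trees whose
#' projection falls within `tol` of the target.  Up to `exhaustive_max` taxa
#' (default 9) the full topology set is enumerated and filtered, which is
#' guaranteed complete.  Beyond that a beam search grows compatible split
#' sets ordered by canonical mask, scoring partial sums by distance to the
#' proportionally scaled target; that regime is a heuristic: three
#' coordinates retain very little of split space, so the beam can and does
#' miss solutions at realistic widths.
#'
#' @param p numeric target point of length `rvs$k`.
#' @param rvs reference set.
#' @param taxa a [taxon_map()].
#' @param tol Euclidean acceptance radius around `p`.
#' @param beam beam width for the heuristic regime (default 64); ignored
#'   when exhaustive.
#' @param exhaustive_max largest n for which the complete topology set is
#'   enumerated and filtered (guaranteed-complete inversion; default 9,
#'   i.e. up to 135,135 candidates).
#' @return list of [ntree()] (possibly empty), sorted by distance to `p`.
#' @export
invert_projection <- function(p, rvs, taxa, tol = 1e-9, beam = 64L,
                              exhaustive_max = 9L) {
  taxa <- as_taxa(taxa)
  n <- taxa$n
  if (length(p) != rvs$k) stop("target point must have k coordinates")
  if (n <= exhaustive_max) {
    trees <- enumerate_trees(taxa)
    pts <- project_batch(trees, rvs)
    dd <- sqrt(rowSums((as.matrix(pts[, 2L + seq_len(rvs$k)]) -
                          matrix(p, nrow(pts), rvs$k, byrow = TRUE))^2))
    keep <- which(dd <= tol)
    return(trees[keep[order(dd[keep])]])
  }
  if (n > 16L) stop("inversion requires n <= 16 (explicit split space)")
  idx <- split_indexer(n)
  entries <- reference_entries(rvs, idx$masks, n)
  states <- list(list(chosen = integer(0), sum = numeric(rvs$k), last = 0L))
  for (depth in seq_len(n - 3L)) {
    cand <- list()
    for (st in states) {
      for (i in seq_len(idx$dim)) {
        if (i <= st$last) next
        m <- idx$masks[i]
        ok <- TRUE
        for (c in st$chosen) {
          if (!splits_compatible(m, idx$masks[c], n)) { ok <- FALSE; break }
        }
        if (!ok) next
        cand[[length(cand) + 1L]] <-
          list(chosen = c(st$chosen, i), sum = st$sum + entries[i, ],
               last = i)
      }
    }
    if (length(cand) == 0L) return(list())
    # partial sums are compared against the proportionally scaled target so
    # early, incomplete sums are not penalized for being short of p
    frac <- depth / (n - 3L)
    sc <- vapply(cand, function(s) sum((s$sum - p * frac)^2), 0)
    states <- cand[order(sc)][seq_len(min(beam, length(cand)))]
  }
  out <- list()
  dd <- numeric(0)
  for (st in states) {
    dist <- sqrt(sum((st$sum - p)^2))
    if (dist <= tol) {
      ss <- new_split_set(idx$masks[st$chosen], taxa)
      out[[length(out) + 1L]] <- splits_to_tree(ss)
      dd <- c(dd, dist)
    }
  }
  out[order(dd)]
}
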