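#' Nearest-neighbor neighborhood of a projected point
#'
#' The focal index together with its m nearest other points by Euclidean
#' distance; ties are broken by ascending point index, so neighborhoods are
#' deterministic.
#'
#' @param points numeric matrix of coordinates, one row per point.
#' @param focal row index of the focal point.
#' @param m neighborhood size, `0 <= m < nrow(points)`.
#' @return integer vector of m + 1 indices, focal first.
#' @export
knn_neighborhood <- function(points, focal, m) {
  points <- rbind(points)
  np <- nrow(points)
  if (m < 0L || m >= np) stop("m must be in [0, number of points - 1]")
  if (focal < 1L || focal > np) stop("focal index out of range")
  if (m == 0L) return(as.integer(focal))
  d2 <- rowSums((points - matrix(points[focal, ], np, ncol(points),
                                 byrow = TRUE))^2)
  ord <- order(d2)              # stable: ties broken by ascending index
  ord <- ord[ord != focal]
  c(as.integer(focal), ord[seq_len(m)])
}

#' Neighborhood-consensus locality experiment
#'
#' Measures how well a projection preserves topological locality: all trees
#' on n taxa are embedded, and for every tree the majority-rule consensus of
#' its m nearest neighbors (plus itself) is computed for m = 0..m_max.  The
#' resolution of that consensus — 1 if the neighborhood agrees on a fully
#' resolved tree, 0 if it agrees on nothing — is aggregated over all focal
#' trees as min/avg/max.  Each replicate redraws the random element of every
#' method (a fresh reference set for the cartographic projection; a fresh
#' random initialization for MDS).
#'
#' Methods: `"cartographic"` (k = 3 hash-table projection), `"mds2"` and
#' `"mds3"` (stress-majorization MDS of the Robinson-Foulds matrix in 2 and
#' 3 dimensions).
#'
#' When the topology count exceeds `subsample`, a seeded subsample of that
#' size is drawn once per replicate and used for *all* methods, keeping the
#' neighborhood candidate pool identical across methods.
#'
#' @param n taxon count (4..8; the full topology set is enumerated).
#' @param m_max largest neighborhood size (default 25).
#' @param replicates number of replicates (default 100, the headline
#'   experiment; use ~10 for CI-scale runs).
#' @param methods subset of `c("cartographic", "mds2", "mds3")`.
#' @param seed base seed; replicate r of the experiment uses `seed + r`.
#' @param d representative-table size for the cartographic method.
#' @param subsample cap on the number of trees per replicate (default 2000;
#'   `Inf` for the full set).
#' @param mds_max_iter iteration cap for the MDS baseline.
#' @return a `locality_table`: data.frame with columns `method`,
#'   `replicate`, `m`, `min`, `avg`, `max`; the configuration is attached as
#'   attribute `config`.
#' @export
locality_experiment <- function(n, m_max = 25L, replicates = 100L,
                                methods = c("cartographic", "mds2", "mds3"),
                                seed = 1L, d = 65535L, subsample = 2000L,
                                mds_max_iter = 50L) {
  n <- as.integer(n)
  if (n < 4L || n > 8L) stop("locality experiment requires 4 <= n <= 8")
  bad <- setdiff(methods, c("cartographic", "mds2", "mds3"))
  if (length(bad)) stop("unknown method: ", paste(bad, collapse = ", "))
  taxa <- as_taxa(n)
  trees <- enumerate_trees(taxa)
  split_lists <- lapply(trees, function(t) tree_splits(t)$masks)
  all_masks <- sort(unique(unlist(split_lists)))
  tsi <- t(vapply(split_lists, function(m) match(m, all_masks),
                  integer(n - 3L)))          # tree x split-index matrix
  rows <- list()
  for (r in seq_len(replicates)) {
    rseed <- as.integer(seed) + r
    if (length(trees) > subsample) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(rseed)
      pick <- sort(sample.int(length(trees), subsample))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    } else {
      pick <- seq_along(trees)
    }
    sub_trees <- trees[pick]
    sub_tsi <- tsi[pick, , drop = FALSE]
    need_rf <- any(c("mds2", "mds3") %in% methods)
    if (need_rf) {
      member <- matrix(0, length(pick), length(all_masks))
      member[cbind(rep(seq_along(pick), each = n - 3L),
                   as.vector(t(sub_tsi)))] <- 1
      Drf <- 2 * (n - 3L) - 2 * tcrossprod(member)
      diag(Drf) <- 0
    }
    for (method in methods) {
      pts <- switch(method,
        cartographic = {
          rvs <- build_reference_set(3L, d, rseed)
          as.matrix(project_batch(sub_trees, rvs)[, c("x", "y", "z")])
        },
        mds2 = mds_embed(Drf, 2L, rseed, max_iter = mds_max_iter)$points,
        mds3 = mds_embed(Drf, 3L, rseed, max_iter = mds_max_iter)$points)
      res <- neighborhood_resolutions(pts, sub_tsi, length(all_masks),
                                      n, m_max)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, replicate = r, m = 0:m_max,
                   min = apply(res, 2L, min),
                   avg = colMeans(res),
                   max = apply(res, 2L, max))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- list(n = n, m_max = m_max, replicates = replicates,
                              methods = methods, seed = seed, d = d,
                              subsample = subsample,
                              mds_max_iter = mds_max_iter)
  class(out) <- c("locality_table", "data.frame")
  out
}

# resolution of the majority consensus over each focal tree's 0..m_max
# nearest neighborhoods; returns a (trees x m_max+1) matrix
neighborhood_resolutions <- function(pts, tsi, n_splits, n, m_max) {
  np <- nrow(pts)
  if (m_max >= np) stop("m_max must be below the number of trees")
  res <- matrix(0, np, m_max + 1L)
  for (focal in seq_len(np)) {
    nb <- knn_neighborhood(pts, focal, m_max)
    cnt <- integer(n_splits)
    for (j in seq_len(m_max + 1L)) {
      s <- tsi[nb[j], ]
      cnt[s] <- cnt[s] + 1L
      res[focal, j] <- sum(cnt > j / 2)
    }
  }
  res / (n - 3L)
}
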