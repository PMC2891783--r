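## Tree bisection and reconnection (TBR) and nearest-neighbor interchange
## (NNI) neighborhoods, at the topology level (deduplicated by canonical
## split set).

# rebuild a valid ntree from a raw edge list over arbitrary vertex ids:
# tips 1..n keep their ids, internal vertices are renumbered n+1..2n-2
ntree_from_edges <- function(edges, taxa) {
  n <- taxa$n
  ids <- sort(unique(as.vector(edges)))
  internal <- ids[ids > n]
  map <- integer(max(ids))
  map[seq_len(n)] <- seq_len(n)
  map[internal] <- n + seq_along(internal)
  ntree(matrix(map[edges], ncol = 2L), taxa)
}

#' TBR neighborhood of a tree
#'
#' All distinct topologies reachable by one tree-bisection-and-reconnection
#' move: a branch is removed, degree-2 vertices are suppressed, and the two
#' components are rejoined by a new branch between any branch of one and any
#' branch of the other (a component that is a single leaf reattaches by its
#' leaf vertex).  The input topology itself is excluded and duplicates are
#' removed by canonical split set.
#'
#' @param t an [ntree()] with n >= 4.
#' @return list of [ntree()].
#' @export
tbr_neighborhood <- function(t) {
  n <- t$taxa$n
  if (n < 4L) stop("TBR requires at least 4 taxa")
  self_key <- topo_key(tree_splits(t)$masks)
  seen <- new.env(parent = emptyenv())
  out <- list()
  edge <- t$edge
  for (i in seq_len(nrow(edge))) {
    u <- edge[i, 1L]
    v <- edge[i, 2L]
    rest <- edge[-i, , drop = FALSE]
    compA <- component_edges(rest, u, n)
    compB <- component_edges(rest, v, n)
    attA <- attachment_options(compA, u)
    attB <- attachment_options(compB, v)
    for (ea in attA) {
      for (eb in attB) {
        edges2 <- rebuild_tbr(compA, compB, ea, eb, u, v)
        cand <- ntree_from_edges(edges2, t$taxa)
        key <- topo_key(tree_splits(cand)$masks)
        if (key == self_key || !is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

# edges of the component containing vertex start, with the cut-end vertex
# suppressed if it now has degree 2
component_edges <- function(edges, start, n) {
  if (nrow(edges) == 0L || !start %in% edges) {
    return(list(edges = matrix(integer(0), 0L, 2L), leaf = start))
  }
  # BFS over the remaining edges
  keep <- logical(nrow(edges))
  seen <- c(start)
  grew <- TRUE
  while (grew) {
    grew <- FALSE
    for (j in seq_len(nrow(edges))) {
      if (keep[j]) next
      a <- edges[j, 1L]
      b <- edges[j, 2L]
      if (a %in% seen || b %in% seen) {
        keep[j] <- TRUE
        seen <- unique(c(seen, a, b))
        grew <- TRUE
      }
    }
  }
  comp <- edges[keep, , drop = FALSE]
  # suppress the old endpoint if it has degree 2 in the component
  inc <- which(comp[, 1L] == start | comp[, 2L] == start)
  if (length(inc) == 2L) {
    nb <- setdiff(as.vector(comp[inc, ]), start)
    comp <- comp[-inc, , drop = FALSE]
    comp <- rbind(comp, nb)
  }
  list(edges = comp, leaf = NULL)
}

# reconnection points: each edge (as a row index), or the bare leaf vertex
attachment_options <- function(comp, cut_end) {
  if (nrow(comp$edges) == 0L) return(list(list(leaf = comp$leaf)))
  lapply(seq_len(nrow(comp$edges)), function(j) list(edge = j))
}

# join the two components with a new branch between attachment points,
# subdividing attachment edges with fresh vertex ids
rebuild_tbr <- function(compA, compB, ea, eb, u, v) {
  fresh <- max(c(compA$edges, compB$edges, u, v)) + 1L
  glue_end <- function(comp, at) {
    if (!is.null(at$leaf)) return(list(edges = comp$edges, node = at$leaf))
    e <- comp$edges[at$edge, ]
    x <- fresh
    fresh <<- fresh + 1L
    edges <- rbind(comp$edges[-at$edge, , drop = FALSE],
                   c(e[1L], x), c(x, e[2L]))
    list(edges = edges, node = x)
  }
  ga <- glue_end(compA, ea)
  gb <- glue_end(compB, eb)
  rbind(ga$edges, gb$edges, c(ga$node, gb$node))
}

#' NNI neighborhood of a tree
#'
#' The 2(n - 3) topologies reachable by one nearest-neighbor interchange
#' (swapping subtrees across an internal branch); a subset of the TBR
#' neighborhood.
#'
#' @param t an [ntree()] with n >= 4.
#' @return list of [ntree()].
#' @export
nni_neighborhood <- function(t) {
  n <- t$taxa$n
  if (n < 4L) stop("NNI requires at least 4 taxa")
  seen <- new.env(parent = emptyenv())
  self_key <- topo_key(tree_splits(t)$masks)
  out <- list()
  edge <- t$edge
  nv <- 2L * n - 2L
  adj <- adjacency_list(edge, nv)
  for (i in seq_len(nrow(edge))) {
    u <- edge[i, 1L]
    v <- edge[i, 2L]
    if (u <= n || v <= n) next  # internal branches only
    au <- setdiff(adj[[u]], v)
    av <- setdiff(adj[[v]], u)
    for (w in av) {
      edges2 <- edge
      # swap subtree au[2] (at u) with subtree w (at v)
      edges2 <- swap_endpoint(edges2, u, au[2L], v, w)
      cand <- ntree_from_edges(edges2, t$taxa)
      key <- topo_key(tree_splits(cand)$masks)
      if (key == self_key || !is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

swap_endpoint <- function(edges, u, a, v, b) {
  for (j in seq_len(nrow(edges))) {
    p <- edges[j, ]
    if (all(sort(p) == sort(c(u, a)))) edges[j, ] <- c(u, b)
    else if (all(sort(p) == sort(c(v, b)))) edges[j, ] <- c(v, a)
  }
  edges
}
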