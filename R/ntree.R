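#' Unrooted binary tree ("n-tree")
#'
#' An n-tree is an unrooted tree over n labeled leaves in which every vertex
#' has degree one or three.  Vertices 1..n are the leaves (leaf i carries
#' taxon i of the taxon map); vertices n+1 .. 2n-2 are internal.  The topology
#' is stored as an undirected edge matrix with 2n-3 rows.
#'
#' @param edge integer matrix with two columns, one row per branch.
#' @param taxa a [taxon_map()].
#' @return an object of class `ntree`.
#' @seealso [read_newick()], [tree_splits()], [splits_to_tree()]
#' @export
ntree <- function(edge, taxa) {
  edge <- matrix(as.integer(edge), ncol = 2L)
  t <- structure(list(edge = edge, taxa = taxa), class = "ntree")
  validate_ntree(t)
  t
}

validate_ntree <- function(t) {
  n <- t$taxa$n
  edge <- t$edge
  if (nrow(edge) != 2L * n - 3L) {
    stop("an n-tree on ", n, " taxa must have ", 2L * n - 3L, " branches, got ",
         nrow(edge))
  }
  nv <- 2L * n - 2L
  if (any(edge < 1L) || any(edge > nv)) stop("vertex id out of range")
  deg <- tabulate(edge, nbins = nv)
  if (any(deg[seq_len(n)] != 1L)) stop("every leaf must have degree 1")
  if (n > 3L && any(deg[(n + 1L):nv] != 3L)) {
    stop("every internal vertex must have degree 3")
  }
  if (n == 3L && deg[4L] != 3L) stop("the 3-taxon star has one degree-3 vertex")
  # connectivity: BFS from vertex 1 must reach all 2n-2 vertices
  adj <- adjacency_list(edge, nv)
  seen <- logical(nv)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  if (!all(seen)) stop("tree is not connected")
  invisible(t)
}

adjacency_list <- function(edge, nv) {
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]
    b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @export
print.ntree <- function(x, ...) {
  cat("ntree on", x$taxa$n, "taxa:", write_newick(x), "\n")
  invisible(x)
}

#' Read a Newick string as an unrooted binary tree
#'
#' Branch lengths and internal node labels are parsed and discarded.  A rooted
#' binary input is unrooted by suppressing the degree-2 root.  Multifurcations
#' (other than the trifurcating representation of an unrooted tree) are
#' rejected.
#'
#' @param text a Newick string (terminating `;` optional for ape).
#' @param taxa optional [taxon_map()]; by default the tip labels sorted
#'   lexicographically.
#' @return an [ntree()].
#' @examples
#' t <- read_newick("((1,2),3,(4,5));")
#' tree_splits(t)
#' @export
read_newick <- function(text, taxa = NULL) {
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse failure: ",
                                          conditionMessage(e)))
  if (is.null(ph)) stop("Newick parse failure")
  phylo_to_ntree(ph, taxa)
}

# Convert an ape phylo object to an ntree, unrooting as needed.
phylo_to_ntree <- function(ph, taxa = NULL) {
  if (anyDuplicated(ph$tip.label)) {
    stop("duplicate taxon labels in tree")
  }
  ph <- ape::unroot(ph)
  if (!ape::is.binary(ph)) stop("tree has multifurcations: not a binary n-tree")
  if (is.null(taxa)) taxa <- taxon_map(ph$tip.label)
  n <- length(ph$tip.label)
  if (n != taxa$n) stop("tree has ", n, " tips but taxon map has ", taxa$n)
  # remap: ape tips are 1..n in ph$tip.label order; we need taxon-map order
  tip_map <- taxon_index(taxa, ph$tip.label)
  nv <- 2L * n - 2L
  vmap <- integer(nv)
  vmap[seq_len(n)] <- tip_map
  vmap[(n + 1L):nv] <- (n + 1L):nv  # ape internal ids already n+1..2n-2
  edge <- matrix(vmap[ph$edge], ncol = 2L)
  ntree(edge, taxa)
}

ntree_to_phylo <- function(t) {
  n <- t$taxa$n
  # root at the internal vertex adjacent to leaf 1 for a deterministic layout
  r <- rooted_children(t)
  build <- function(v) {
    if (v <= n) return(t$taxa$labels[v])
    paste0("(", paste(vapply(r$children[[v]], build, ""), collapse = ","), ")")
  }
  txt <- paste0(build(r$root), ";")
  ape::read.tree(text = txt)
}

# Orient the tree away from the internal vertex adjacent to leaf 1.
# Returns root id, children lists, and a breadth-first vertex order.
rooted_children <- function(t) {
  n <- t$taxa$n
  nv <- 2L * n - 2L
  adj <- adjacency_list(t$edge, nv)
  root <- if (n == 3L) 4L else adj[[1L]][1L]
  parent <- integer(nv)
  children <- vector("list", nv)
  order <- integer(nv)
  order[1L] <- root
  parent[root] <- 0L
  k <- 1L
  i <- 1L
  while (i <= k) {
    v <- order[i]
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        children[[v]] <- c(children[[v]], w)
        k <- k + 1L
        order[k] <- w
      }
    }
    i <- i + 1L
  }
  list(root = root, parent = parent, children = children, order = order[1:k])
}

#' Write an unrooted tree as Newick
#'
#' Emits the trifurcating-root unrooted form, without branch lengths.
#'
#' @param t an [ntree()].
#' @return a Newick string.
#' @export
write_newick <- function(t) {
  n <- t$taxa$n
  r <- rooted_children(t)
  build <- function(v) {
    if (v <= n) return(t$taxa$labels[v])
    paste0("(", paste(vapply(r$children[[v]], build, ""), collapse = ","), ")")
  }
  kids <- setdiff(r$children[[r$root]], 1L)
  paste0("(", t$taxa$labels[1L], ",",
         paste(vapply(kids, build, ""), collapse = ","), ");")
}
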