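#' Simulate a DNA alignment on a tree
#'
#' Evolves sites independently down the tree (rooted at the internal vertex
#' adjacent to taxon 1) under a symmetric single-parameter process: on each
#' branch a site changes with probability `p_change`, and a changing site
#' picks one of the three other nucleotides uniformly.  The root state is
#' uniform over A, C, G, T.  This is deliberately the simplest process that
#' induces parsimony score structure over topologies; it makes no claim of
#' evolutionary realism (no rate variation, no GTR, no branch lengths).
#'
#' @param t an [ntree()] (the generating topology).
#' @param sites number of sites (>= 1).
#' @param p_change per-branch change probability in `[0, 0.75]`.
#' @param seed integer seed; the alignment is reproducible from it.
#' @return an [alignment()] over `t`'s taxa.
#' @export
simulate_alignment <- function(t, sites, p_change, seed = 1L) {
  if (p_change < 0 || p_change > 0.75) {
    stop("p_change must be in [0, 0.75]")
  }
  if (sites < 1L) stop("need at least one site")
  n <- t$taxa$n
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  r <- rooted_children(t)
  nv <- 2L * n - 2L
  state <- matrix(0L, nv, sites)  # states coded 1..4
  state[r$root, ] <- sample.int(4L, sites, replace = TRUE)
  for (v in r$order[-1L]) {
    p <- state[r$parent[v], ]
    flip <- stats::runif(sites) < p_change
    shift <- sample.int(3L, sites, replace = TRUE)
    state[v, ] <- ifelse(flip, ((p - 1L + shift) %% 4L) + 1L, p)
  }
  masks <- c(1L, 2L, 4L, 8L)[state[seq_len(n), , drop = FALSE]]
  structure(list(taxa = t$taxa,
                 states = matrix(as.integer(masks), nrow = n),
                 sites = as.integer(sites)),
            class = "alignment")
}
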