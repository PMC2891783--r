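#' Metric multidimensional scaling by stress majorization (SMACOF)
#'
#' Embeds items with a given symmetric dissimilarity matrix into 2 or 3
#' dimensions by minimizing the raw stress, the sum of squared differences
#' between the given and embedded distances.  Uses the Guttman transform,
#' whose majorization property guarantees a non-increasing stress sequence;
#' the full sequence is recorded.  Initialization is uniform random from the
#' seeded stream, matching the random element of the baseline this
#' reimplements.
#'
#' @param dist symmetric, zero-diagonal dissimilarity matrix (e.g.
#'   [rf_matrix()]).
#' @param dims 2 or 3.
#' @param seed integer seed for the random initialization.
#' @param max_iter iteration cap (default 100).
#' @param tol relative stress-improvement threshold for convergence.
#' @return object of class `mds_embedding`: `points` (N x dims), `stress`
#'   (per-iteration sequence), `converged`, `dims`, `seed`.
#' @export
mds_embed <- function(dist, dims = 2L, seed = 1L, max_iter = 100L,
                      tol = 1e-6) {
  D <- as.matrix(dist)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12)) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  N <- nrow(D)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  span <- max(D)
  if (span == 0) span <- 1
  X <- matrix(stats::runif(N * dims, -span / 2, span / 2), N, dims)
  edist <- function(X) {
    G <- tcrossprod(X)
    sq <- diag(G)
    E <- sqrt(pmax(outer(sq, sq, "+") - 2 * G, 0))
    diag(E) <- 0
    E
  }
  E <- edist(X)
  stress <- sum((D - E)^2) / 2
  trace <- stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    R <- ifelse(E > 0, D / E, 0)
    diag(R) <- 0
    B <- -R
    diag(B) <- rowSums(R)
    X <- B %*% X / N
    E <- edist(X)
    s2 <- sum((D - E)^2) / 2
    trace <- c(trace, s2)
    if (stress - s2 <= tol * max(stress, .Machine$double.eps)) {
      stress <- s2
      converged <- TRUE
      break
    }
    stress <- s2
  }
  structure(list(points = X, stress = trace, converged = converged,
                 dims = dims, seed = as.integer(seed)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("mds_embedding:", nrow(x$points), "points in", x$dims, "dims; stress",
      format(utils::tail(x$stress, 1), digits = 6),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}
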