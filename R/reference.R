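#' Build a hash-table-backed reference vector set
#'
#' The cartographic projection needs k reference vectors spanning split
#' space, whose dimension 2^(n-1) - n - 1 makes explicit storage infeasible.
#' Instead, k representative vectors of fixed length d are stored, and entry
#' i of reference vector j is read as `representatives[h(i) mod d, j]`.
#'
#' Representatives are drawn with uniform(-1, 1) entries from R's seeded
#' Mersenne-Twister stream, orthogonalized with classical Gram-Schmidt, and
#' rescaled so every column has the magnitude of the first (true unit
#' normalization would underflow at split-space dimension, so equal magnitude
#' is enforced instead).
#'
#' @param k number of output dimensions (default 3).
#' @param d representative-table size (default 65535).
#' @param seed integer seed; the construction is reproducible from it.
#' @param scheme a [hash_scheme()].
#' @return object of class `reference_set`: fields `k`, `d`, `seed`,
#'   `scheme`, and the d x k representative matrix `R`.
#' @export
build_reference_set <- function(k = 3L, d = 65535L, seed = 1L,
                                scheme = hash_scheme("jenkins_oaat")) {
  k <- as.integer(k)
  d <- as.integer(d)
  if (k < 2L) stop("k must be at least 2")
  if (d < k) stop("table size d must be at least k (Gram-Schmidt degenerates)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  R <- matrix(stats::runif(d * k, -1, 1), nrow = d, ncol = k)
  for (j in seq_len(k)[-1L]) {
    for (i in seq_len(j - 1L)) {
      R[, j] <- R[, j] - sum(R[, i] * R[, j]) / sum(R[, i]^2) * R[, i]
    }
  }
  m1 <- sqrt(sum(R[, 1L]^2))
  for (j in seq_len(k)[-1L]) {
    R[, j] <- R[, j] * (m1 / sqrt(sum(R[, j]^2)))
  }
  structure(list(k = k, d = d, seed = as.integer(seed), scheme = scheme,
                 R = R),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set: k =", x$k, ", d =", x$d, ", hash =", x$scheme$name,
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Reference set with explicitly assigned per-split coordinates
#'
#' For worked examples and tiny spaces the per-split reference coordinates
#' can be given directly instead of through a hash table.  Splits without an
#' assigned entry contribute the zero vector (documented behaviour; supply
#' all splits you intend to project).
#'
#' @param sides list of character vectors naming one side of each split.
#' @param coords numeric matrix, one row per split in `sides`, k columns.
#' @param taxa a [taxon_map()].
#' @return object of class `explicit_reference_set`.
#' @examples
#' tm <- taxon_map(as.character(1:5), sort = FALSE)
#' rvs <- explicit_reference_set(list(c("1", "2"), c("4", "5")),
#'                               rbind(c(1.0, 0.9), c(-0.3, 0.6)), tm)
#' project(read_newick("((1,2),3,(4,5));", tm), rvs)  # (0.7, 1.5)
#' @export
explicit_reference_set <- function(sides, coords, taxa) {
  coords <- rbind(coords)
  if (length(sides) != nrow(coords)) {
    stop("need one coordinate row per split")
  }
  masks <- vapply(sides, function(s) canonical_split(taxon_index(taxa, s),
                                                     taxa$n), 0L)
  if (anyDuplicated(masks)) stop("duplicate splits")
  structure(list(k = ncol(coords), taxa = taxa, masks = masks,
                 coords = coords),
            class = "explicit_reference_set")
}

#' Per-split reference-vector entries
#'
#' The k-vector a split contributes to a tree's projection: for a hash-backed
#' set, row `h(split) mod d` of the representative matrix; for an explicit
#' set, the assigned coordinates (zero if unassigned).
#'
#' @param rvs a [build_reference_set()] or [explicit_reference_set()].
#' @param masks canonical split mask(s).
#' @param n taxon count (ignored for explicit sets, which carry their taxa).
#' @return numeric matrix, one row per mask, k columns.
#' @export
reference_entries <- function(rvs, masks, n) {
  UseMethod("reference_entries")
}

#' @export
reference_entries.reference_set <- function(rvs, masks, n) {
  slots <- rvs$scheme$fun(masks, n, rvs$d)
  rvs$R[slots + 1L, , drop = FALSE]
}

#' @export
reference_entries.explicit_reference_set <- function(rvs, masks, n) {
  out <- matrix(0, nrow = length(masks), ncol = rvs$k)
  hit <- match(as.integer(masks), rvs$masks)
  out[!is.na(hit), ] <- rvs$coords[hit[!is.na(hit)], , drop = FALSE]
  out
}
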