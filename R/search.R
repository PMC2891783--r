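#' Parsimony score spectrum of a TBR neighborhood
#'
#' Scores every topology within one TBR rearrangement of `t` and tabulates
#' the scores.  Reproduces, at toy scale, the observation that most
#' one-rearrangement neighbors of a good tree are much worse than the tree
#' itself.
#'
#' @param t an [ntree()].
#' @param a an [alignment()] over the same taxa.
#' @return object of class `score_spectrum`: `focal_score`, `scores`
#'   (integer vector over the neighborhood), `histogram` (a `table`).
#' @export
score_spectrum <- function(t, a) {
  stop_unless_same_taxa(t$taxa, a$taxa)
  nb <- tbr_neighborhood(t)
  cp <- compress_patterns(a$states)
  scores <- vapply(nb, fitch_score_patterns, 0L, pat = cp$states,
                   w = cp$weights)
  structure(list(focal_score = fitch_score(t, a),
                 scores = scores,
                 histogram = table(scores)),
            class = "score_spectrum")
}

#' @export
print.score_spectrum <- function(x, ...) {
  cat("score_spectrum: focal score", x$focal_score, "over",
      length(x$scores), "TBR neighbors; mode",
      spectrum_mode(x), "\n")
  invisible(x)
}

#' Modal score of a spectrum
#'
#' @param sp a `score_spectrum`.
#' @return the most frequent neighbor score (smallest such score on ties).
#' @export
spectrum_mode <- function(sp) {
  h <- sp$histogram
  as.integer(names(h)[which.max(h)])
}

#' Steepest-descent parsimony search over TBR neighborhoods
#'
#' From the start tree, repeatedly moves to the best-scoring TBR neighbor
#' until no neighbor improves on the current tree (plain hill climbing on
#' the negated score).  Ties among equally best neighbors are broken by the
#' lowest canonical split-set encoding, so the search is deterministic.
#' Every `sampling_period`-th evaluated rearrangement is recorded with its
#' score, giving a sampled picture of the rejected trees alongside the
#' accepted path.
#'
#' @param a an [alignment()].
#' @param start an [ntree()] over the same taxa.
#' @param sampling_period record every this-many-th evaluated neighbor
#'   (default 100).
#' @param seed accepted for interface uniformity; the search itself is
#'   deterministic.
#' @return object of class `search_trace`: `accepted` (list of trees),
#'   `accepted_scores` (strictly decreasing after the start entry),
#'   `sampled` (list of trees), `sampled_scores`, `sampling_period`,
#'   `evaluations`.
#' @export
hill_climb <- function(a, start, sampling_period = 100L, seed = NULL) {
  stop_unless_same_taxa(a$taxa, start$taxa)
  if (sampling_period < 1L) stop("sampling period must be >= 1")
  cp <- compress_patterns(a$states)
  current <- start
  cur_score <- fitch_score_patterns(current, cp$states, cp$weights)
  accepted <- list(current)
  accepted_scores <- cur_score
  sampled <- list()
  sampled_scores <- integer(0)
  evals <- 0L
  repeat {
    nb <- tbr_neighborhood(current)
    keys <- vapply(nb, function(x) topo_key(tree_splits(x)$masks), "")
    nb <- nb[order(keys, method = "radix")]
    best <- NULL
    best_score <- cur_score
    for (cand in nb) {
      s <- fitch_score_patterns(cand, cp$states, cp$weights)
      evals <- evals + 1L
      if (evals %% sampling_period == 0L) {
        sampled[[length(sampled) + 1L]] <- cand
        sampled_scores <- c(sampled_scores, s)
      }
      if (s < best_score) {  # strict: first hit in canonical order wins ties
        best <- cand
        best_score <- s
      }
    }
    if (is.null(best)) break
    current <- best
    cur_score <- best_score
    accepted[[length(accepted) + 1L]] <- current
    accepted_scores <- c(accepted_scores, cur_score)
  }
  structure(list(accepted = accepted, accepted_scores = accepted_scores,
                 sampled = sampled, sampled_scores = sampled_scores,
                 sampling_period = as.integer(sampling_period),
                 evaluations = evals),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat("search_trace:", length(x$accepted), "accepted trees (scores",
      paste(x$accepted_scores, collapse = " -> "), "),",
      length(x$sampled), "sampled rejections over", x$evaluations,
      "evaluations\n")
  invisible(x)
}

#' Exhaustive parsimony search
#'
#' Scores every topology (for n small enough to enumerate) and returns the
#' optimum.
#'
#' @param a an [alignment()] with 4 <= n <= 9 taxa.
#' @return list with `best_score`, `best_trees` (all optima), `n_scored`.
#' @export
exhaustive_search <- function(a) {
  n <- a$taxa$n
  if (n > 9L) stop("exhaustive search is capped at 9 taxa")
  cp <- compress_patterns(a$states)
  best_score <- Inf
  best <- list()
  count <- 0L
  enumerate_trees(a$taxa, FUN = function(t) {
    s <- fitch_score_patterns(t, cp$states, cp$weights)
    count <<- count + 1L
    if (s < best_score) {
      best_score <<- s
      best <<- list(t)
    } else if (s == best_score) {
      best[[length(best) + 1L]] <<- t
    }
  })
  list(best_score = as.integer(best_score), best_trees = best,
       n_scored = count)
}
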