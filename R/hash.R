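#' Serialize a split for hashing
#'
#' Deterministic, platform-stable byte key for a canonical split: the taxon
#' count n followed by the sorted 0-based positions of the canonical side,
#' each as a 4-byte big-endian integer.  Injective over the splits of a fixed
#' taxon map.
#'
#' @param mask canonical split mask.
#' @param n taxon count.
#' @return a raw vector.
#' @export
split_key <- function(mask, n) {
  side0 <- mask_to_side(mask, n) - 1L
  writeBin(c(as.integer(n), side0), raw(), size = 4L, endian = "big")
}

#' Hash schemes for the table-backed reference vectors
#'
#' A hash scheme maps a split to a nonnegative integer, which is reduced
#' modulo the representative-table size d to a slot.  Two schemes ship with
#' the package:
#'
#' * `"jenkins_oaat"` (default): Bob Jenkins' one-at-a-time 32-bit hash of
#'   [split_key()].
#' * `"modulo_sum"`: the didactic toy scheme — the sum of the 1-based taxon
#'   positions on the *smaller* side of the split (ties between equal-sized
#'   sides broken toward the canonical side).  With d = 3 and 5 taxa this
#'   reproduces the printed worked example: the splits {1,2} and {4,5} both
#'   hash to slot 0.
#'
#' @param name `"jenkins_oaat"` or `"modulo_sum"`.
#' @return an object of class `hash_scheme`; its `fun(masks, n, d)` returns
#'   0-based slots.
#' @export
hash_scheme <- function(name = c("jenkins_oaat", "modulo_sum")) {
  name <- match.arg(name)
  fun <- switch(name,
    jenkins_oaat = function(masks, n, d) {
      keys <- lapply(as.integer(masks), split_key, n = n)
      as.integer(oaat_hash(keys) %% d)
    },
    modulo_sum = function(masks, n, d) {
      vapply(as.integer(masks), function(m) {
        side <- mask_to_side(m, n)
        if (2L * length(side) > n) side <- setdiff(seq_len(n), side)
        as.integer(sum(side) %% d)
      }, 0L)
    }
  )
  structure(list(name = name, fun = fun), class = "hash_scheme")
}

#' @export
print.hash_scheme <- function(x, ...) {
  cat("hash_scheme:", x$name, "\n")
  invisible(x)
}
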