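#' Taxon map
#'
#' An ordered set of taxon labels.  The position of a label in the map (1-based
#' in R, 0-based in serialized split keys) defines the taxon index used by
#' every split-space operation, so two trees can only be compared when they
#' share an identical taxon map.
#'
#' @param labels character vector of unique taxon names, length >= 3.
#' @param sort if `TRUE` (the default when labels come from parsed input),
#'   labels are sorted lexicographically in the C locale before indexing;
#'   pass `FALSE` to keep the supplied order.
#' @return an object of class `taxon_map` with fields `labels` and `n`.
#' @examples
#' taxon_map(c("3", "1", "2"))          # sorted: "1" "2" "3"
#' taxon_map(c("b", "a"), sort = FALSE) # error: n >= 3 required
#' @export
taxon_map <- function(labels, sort = TRUE) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(labels) < 3L) stop("a taxon map needs at least 3 taxa")
  if (length(labels) > 30L) stop("taxon maps are capped at 30 taxa")
  if (sort) labels <- sort(labels, method = "radix")
  structure(list(labels = labels, n = length(labels)), class = "taxon_map")
}

#' @export
print.taxon_map <- function(x, ...) {
  cat("taxon_map with", x$n, "taxa:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

taxon_index <- function(taxa, labels) {
  idx <- match(labels, taxa$labels)
  if (anyNA(idx)) {
    stop("unknown taxa: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

same_taxa <- function(a, b) identical(a$labels, b$labels)

stop_unless_same_taxa <- function(a, b) {
  if (!same_taxa(a, b)) stop("trees do not share a taxon map")
  invisible(TRUE)
}
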