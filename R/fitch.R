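## DNA alignments as IUPAC state-set bitmasks (A=1, C=2, G=4, T=8) and the
## Fitch small-parsimony algorithm.

iupac_masks <- c(a = 1L, c = 2L, g = 4L, t = 8L, u = 8L,
                 r = 5L, y = 10L, s = 6L, w = 9L, k = 12L, m = 3L,
                 b = 14L, d = 13L, h = 11L, v = 7L,
                 n = 15L, "-" = 15L, "?" = 15L)

#' DNA alignment
#'
#' Sequences are stored as state-set bitmasks over {A, C, G, T}; IUPAC
#' ambiguity codes map to the corresponding sets, and gaps (`-`, `?`, `N`)
#' to the full set (standard Fitch practice).
#'
#' @param seqs named character vector of equal-length DNA strings (names are
#'   taxon labels), or a character matrix with one row per taxon.
#' @param taxa optional [taxon_map()]; defaults to the sequence names sorted
#'   lexicographically.
#' @return object of class `alignment`: `taxa`, `states` (n x sites integer
#'   matrix), `sites`.
#' @export
alignment <- function(seqs, taxa = NULL) {
  if (is.matrix(seqs)) {
    chars <- seqs
    labels <- rownames(seqs)
  } else {
    labels <- names(seqs)
    if (is.null(labels)) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    chars <- do.call(rbind, strsplit(tolower(as.character(seqs)), ""))
    rownames(chars) <- labels
  }
  if (is.null(taxa)) taxa <- taxon_map(labels)
  ord <- taxon_index(taxa, labels)
  states <- matrix(NA_integer_, nrow = taxa$n, ncol = ncol(chars))
  codes <- iupac_masks[tolower(chars)]
  if (anyNA(codes)) {
    stop("unknown residue(s): ",
         paste(unique(chars[is.na(codes)]), collapse = " "))
  }
  states[ord, ] <- matrix(as.integer(codes), nrow = nrow(chars))
  if (anyNA(states)) stop("alignment does not cover every taxon")
  structure(list(taxa = taxa, states = states, sites = ncol(states)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", x$taxa$n, "taxa x", x$sites, "sites\n")
  invisible(x)
}

#' Read a FASTA alignment
#'
#' @param file path to an uncompressed FASTA file of aligned DNA.
#' @param taxa optional [taxon_map()].
#' @return an [alignment()].
#' @export
read_fasta <- function(file, taxa = NULL) {
  dna <- ape::read.FASTA(file)
  chars <- as.character(dna)
  seqs <- vapply(chars, paste, "", collapse = "")
  alignment(seqs, taxa)
}

#' Write an alignment as FASTA
#'
#' @param a an [alignment()].
#' @param file output path.
#' @export
write_fasta <- function(a, file) {
  letters4 <- c("a", "c", "g", "t")
  rev_map <- character(15L)
  for (nm in names(iupac_masks)) {
    if (!nm %in% c("u", "-", "?")) rev_map[iupac_masks[[nm]]] <- nm
  }
  lines <- character(2L * a$taxa$n)
  for (i in seq_len(a$taxa$n)) {
    lines[2L * i - 1L] <- paste0(">", a$taxa$labels[i])
    lines[2L * i] <- paste(toupper(rev_map[a$states[i, ]]), collapse = "")
  }
  writeLines(lines, file)
  invisible(file)
}

# collapse duplicate site patterns; returns states (n x patterns) + weights
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = states[, first, drop = FALSE], weights = w)
}

#' Fitch parsimony score
#'
#' The minimum number of character-state changes over all sites, by the
#' Fitch downpass on a copy rooted at the internal vertex adjacent to taxon
#' 1 (the score is independent of the rooting).  Site patterns are collapsed
#' with weights before scoring.
#'
#' @param t an [ntree()].
#' @param a an [alignment()] over the same taxon map.
#' @return a nonnegative integer.
#' @export
fitch_score <- function(t, a) {
  stop_unless_same_taxa(t$taxa, a$taxa)
  if (a$sites == 0L) stop("empty alignment")
  cp <- compress_patterns(a$states)
  fitch_score_patterns(t, cp$states, cp$weights)
}

fitch_score_patterns <- function(t, pat, w) {
  n <- t$taxa$n
  r <- rooted_children(t)
  nv <- 2L * n - 2L
  S <- matrix(0L, nv, ncol(pat))
  score <- 0
  for (v in rev(r$order)) {
    if (v <= n) {
      S[v, ] <- pat[v, ]
    } else {
      kids <- r$children[[v]]
      acc <- S[kids[1L], ]
      for (w2 in kids[-1L]) {
        s <- S[w2, ]
        inter <- bitwAnd(acc, s)
        miss <- inter == 0L
        score <- score + sum(w[miss])
        acc <- ifelse(miss, bitwOr(acc, s), inter)
      }
      S[v, ] <- acc
    }
  }
  as.integer(score)
}
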