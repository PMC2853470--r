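#' @title Connectivity fingerprints and Tanimoto similarity
#' @description
#' Fixed-length bit fingerprints hashed from linear heavy-atom paths
#' (element and bond-order sequences, up to a maximum path length). The
#' fingerprint sees only the connectivity graph, never stereochemistry, so
#' stereoisomers map to identical fingerprints — which is what makes
#' tied-rank structure clustering collapse them.
#' @name fingerprint-model
NULL

# deterministic polynomial string hash -> bit position in [1, nbits]
.fp_hash <- function(s, nbits) {
  v <- utf8ToInt(s)
  h <- 7
  for (x in v) h <- (h * 31 + x) %% 2147483647
  (h %% nbits) + 1L
}

#' Compute a path-based connectivity fingerprint
#'
#' Enumerates all simple paths of 1..`max_len` heavy atoms; each path's
#' element/bond-order string (read in its lexicographically smaller
#' direction) sets one hashed bit.
#'
#' @param m an `fr_mol`.
#' @param nbits fingerprint length in bits (default 1024).
#' @param max_len maximum path length in atoms (default 5).
#' @return an `fr_fingerprint`: logical vector of length `nbits`.
#' @export
fingerprint <- function(m, nbits = 1024L, max_len = 5L) {
  stopifnot(inherits(m, "fr_mol"))
  n <- nrow(m$atoms)
  bits <- logical(nbits)
  el <- m$atoms$element
  # adjacency with bond orders
  nbr <- vector("list", n)
  if (nrow(m$bonds)) {
    for (i in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a1[i]; b <- m$bonds$a2[i]; o <- m$bonds$order[i]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  paths <- character(0)
  walk <- function(path, labels) {
    fwd <- paste(labels, collapse = "")
    rev_ <- paste(rev(labels), collapse = "")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if (length(path) >= max_len) return()
    last <- path[length(path)]
    nb <- nbr[[last]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      nxt <- nb[k, 1]
      if (nxt %in% path) next
      walk(c(path, nxt), c(labels, nb[k, 2], el[nxt]))
    }
  }
  for (a in seq_len(n)) walk(a, el[a])
  for (p in unique(paths)) bits[.fp_hash(p, nbits)] <- TRUE
  structure(bits, class = "fr_fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; 1 for identical non-empty fingerprints. Two
#' all-zero fingerprints compare as 0 with a warning.
#'
#' @param a,b `fr_fingerprint` (or logical) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints are empty; similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  sum(a & b) / u
}
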