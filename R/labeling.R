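# Window labelling: canonical Huffman code-length profiles over base
# composition. The label, not the codes, is the point: two windows with the
# same label have similar composition and are pooled into one bin.

#' DNA alphabet used throughout the codec
#'
#' The fixed, ordered alphabet over which genomes are encoded: the four
#' nucleotides plus `N` for uncalled bases. The order is significant — it is
#' the final tie-break when symbols have equal code length and equal
#' frequency, so it must not change within a codec run.
#'
#' @format A character vector of single characters, `c("A","C","G","T","N")`.
#' @export
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# 256-entry lookup: byte value -> 1-based symbol index (0 = not in alphabet)
.alphabet_lookup <- function(alphabet) {
  code <- integer(256L)
  code[as.integer(charToRaw(paste(alphabet, collapse = ""))) + 1L] <-
    seq_along(alphabet)
  code
}

.check_alphabet <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) == 0L)
    stop("alphabet must be a non-empty character vector")
  if (any(nchar(alphabet) != 1L))
    stop("alphabet symbols must be single characters")
  if (anyDuplicated(alphabet))
    stop("alphabet symbols must be unique")
  invisible(alphabet)
}

#' Count symbol frequencies in a window
#'
#' @param window A single non-empty string over `alphabet`.
#' @param alphabet Ordered alphabet (default [DNA_ALPHABET]).
#' @return A named integer vector with one entry per alphabet symbol (zeros
#'   for absent symbols); the frequency table of the window.
#' @examples
#' count_symbols("GGGGA")
#' @export
count_symbols <- function(window, alphabet = DNA_ALPHABET) {
  .check_alphabet(alphabet)
  if (!is.character(window) || length(window) != 1L || is.na(window))
    stop("window must be a single string")
  if (nchar(window) == 0L) stop("empty window")
  code <- .alphabet_lookup(alphabet)
  idx <- code[as.integer(charToRaw(window)) + 1L]
  if (any(idx == 0L)) {
    off <- which(idx == 0L)[1L]
    stop(sprintf("character '%s' at offset %d is not in the alphabet",
                 substr(window, off, off), off - 1L))
  }
  counts <- tabulate(idx, nbins = length(alphabet))
  names(counts) <- alphabet
  counts
}

# Huffman code lengths for positive weights, deterministic tie-breaking:
# at each step merge the two nodes with (lowest weight, earliest creation).
# Leaves are created first, in input (= alphabet) order; internal nodes get
# increasing creation stamps. Returns depths in input order. A single node
# gets length 1 (a real emitted code needs at least one bit).
.huffman_lengths <- function(weights) {
  m <- length(weights)
  if (m == 0L) stop("no positive weights")
  if (m == 1L) return(1L)
  n_total <- 2L * m - 1L
  wts <- numeric(n_total)
  wts[seq_len(m)] <- as.numeric(weights)
  created <- seq_len(n_total)
  members <- vector("list", n_total)
  members[seq_len(m)] <- as.list(seq_len(m))
  depth <- integer(m)
  active <- seq_len(m)
  nxt <- m
  while (length(active) > 1L) {
    ord <- order(wts[active], created[active])
    i <- active[ord[1L]]
    j <- active[ord[2L]]
    nxt <- nxt + 1L
    wts[nxt] <- wts[i] + wts[j]
    members[[nxt]] <- c(members[[i]], members[[j]])
    depth[members[[nxt]]] <- depth[members[[nxt]]] + 1L
    active <- c(active[-ord[1:2]], nxt)
  }
  depth
}

#' Assign canonical Huffman code lengths to a frequency table
#'
#' Builds a Huffman tree over the symbols with positive count, merging the
#' two lowest-weight nodes at each step with deterministic tie-breaking
#' (lower weight first, then earlier node creation, then alphabet order),
#' and returns the resulting code lengths. Codes themselves are never
#' materialized — only their lengths feed the bin label. A window containing
#' a single distinct symbol gets length 1.
#'
#' @param freqs A frequency table as returned by [count_symbols()]: named
#'   non-negative integer counts in alphabet order, at least one positive.
#' @return Named integer vector of code lengths, one per *present* symbol,
#'   in alphabet order. Satisfies the Kraft inequality (with equality when
#'   two or more symbols are present) and attains the optimal prefix-code
#'   weighted length.
#' @examples
#' assign_code_lengths(count_symbols("GGGGGGGGAAAATTC"))
#' @export
assign_code_lengths <- function(freqs) {
  if (is.null(names(freqs)) || any(is.na(freqs)) || any(freqs < 0))
    stop("freqs must be a named vector of non-negative counts")
  present <- freqs > 0
  if (!any(present)) stop("frequency table has no positive counts")
  len <- .huffman_lengths(freqs[present])
  names(len) <- names(freqs)[present]
  len
}

#' Build a window's bin label from its code-length assignment
#'
#' Symbols are ordered by (code length ascending, frequency descending,
#' alphabet order), the first `min(k, number present)` are kept, and the
#' label is formatted `"<symbols>_<digits>"` — e.g. a window whose Huffman
#' schema is G:1 bit, A:2, T:3, C:3 labels as `"GATC_1233"` at `k = 4`,
#' `"GA_12"` at `k = 2`, `"G_1"` at `k = 1`. Smaller `k` means coarser
#' labels, hence fewer bins.
#'
#' @param cla Code lengths from [assign_code_lengths()] (named, present
#'   symbols in alphabet order).
#' @param freqs The frequency table the lengths were derived from.
#' @param k Label length: number of leading (shortest-code) symbols kept.
#' @return The label string.
#' @export
make_label <- function(cla, freqs, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("k must be a positive integer")
  syms <- names(cla)
  f <- as.numeric(freqs[syms])
  ord <- order(cla, -f, method = "radix")  # stable: alphabet order last
  keep <- seq_len(min(as.integer(k), length(syms)))
  paste0(paste(syms[ord][keep], collapse = ""), "_",
         paste(cla[ord][keep], collapse = ""))
}

# Vectorized labelling used by the binner: one label per row of a window
# count matrix (rows = windows, cols = alphabet symbols). Deduplicates
# identical count rows so the Huffman construction runs once per distinct
# composition.
.labels_from_counts <- function(counts, k, alphabet) {
  keys <- do.call(paste, c(lapply(seq_len(ncol(counts)), function(j) counts[, j]),
                           sep = ","))
  uidx <- which(!duplicated(keys))
  ulab <- vapply(uidx, function(i) {
    cts <- counts[i, ]
    present <- cts > 0L
    len <- .huffman_lengths(cts[present])
    names(len) <- alphabet[present]
    make_label(len, stats::setNames(cts, alphabet), k)
  }, character(1L))
  ulab[match(keys, keys[uidx])]
}
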