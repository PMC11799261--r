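# Scan-classify-bin pass over a one-line genome and its exact inverse.

#' Codec parameters
#'
#' Bundles the tunables of a codec run: window length `w`, label length `k`,
#' backend codec, and alphabet. Defaults (`w = 250`, `k = 2`, bzip2) are the
#' best-performing bundled configuration on genome-scale input.
#'
#' @param w Window length in bases (>= 1). Windows of 250–1000 bases tend to
#'   capture local composition skew; much shorter or longer windows see
#'   near-uniform base frequencies.
#' @param k Label length (>= 1): leading symbols of the code-length profile
#'   kept in the bin key. Larger `k` means more, purer bins.
#' @param backend Backend codec id, one of [list_backends()].
#' @param alphabet Ordered alphabet; see [DNA_ALPHABET].
#' @return An object of class `ost_params`.
#' @export
codec_params <- function(w = 250L, k = 2L, backend = "bzip2",
                         alphabet = DNA_ALPHABET) {
  .check_alphabet(alphabet)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 1)
    stop("w must be a positive integer")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("k must be a positive integer")
  if (!backend %in% list_backends())
    stop(sprintf("unknown backend '%s' (registered: %s)",
                 backend, paste(list_backends(), collapse = ", ")))
  structure(list(w = as.integer(w), k = as.integer(k), backend = backend,
                 alphabet = alphabet),
            class = "ost_params")
}

#' @export
print.ost_params <- function(x, ...) {
  cat(sprintf("OST codec parameters: w = %d, k = %d, backend = %s, alphabet = %s\n",
              x$w, x$k, x$backend, paste(x$alphabet, collapse = "")))
  invisible(x)
}

#' Split a genome into non-overlapping windows
#'
#' Left-to-right windows of length `w`; the final window is shorter when the
#' text length is not a multiple of `w`. Concatenating the windows
#' reproduces the input.
#'
#' @param text A non-empty string.
#' @param w Window length.
#' @return Character vector of windows.
#' @export
split_windows <- function(text, w) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("text must be a single string")
  t <- nchar(text)
  if (t == 0L) stop("empty text")
  w <- as.integer(w)
  if (w < 1L) stop("w must be a positive integer")
  starts <- seq.int(1L, t, by = w)
  substring(text, starts, pmin(starts + w - 1L, t))
}

# Window-by-symbol count matrix for the whole text in one pass.
# Errors identify the offending character, its 0-based text offset, and the
# 1-based window index.
.window_count_matrix <- function(text, w, alphabet) {
  code <- .alphabet_lookup(alphabet)
  idx <- code[as.integer(charToRaw(text)) + 1L]
  if (any(idx == 0L)) {
    off <- which(idx == 0L)[1L]
    stop(sprintf(
      "character '%s' at offset %d (window %d) is not in the alphabet",
      substr(text, off, off), off - 1L, (off - 1L) %/% w + 1L))
  }
  t <- length(idx)
  nwin <- (t + w - 1L) %/% w
  win <- (seq_len(t) - 1L) %/% w + 1L
  counts <- tabulate(win + nwin * (idx - 1L), nbins = nwin * length(alphabet))
  dim(counts) <- c(nwin, length(alphabet))
  counts
}

#' Classify and bin a genome's windows
#'
#' The forward pass of the codec: the text is cut into non-overlapping
#' windows of length `w`, each window is labelled by its canonical Huffman
#' code-length profile truncated to `k` symbols, windows sharing a label are
#' concatenated (in order of appearance) into one bin, and the per-window
#' label sequence `L` is retained for reassembly. Bins are keyed in order of
#' first appearance of their label, which makes downstream archives
#' deterministic.
#'
#' @param text One-line genome over the alphabet.
#' @param params [codec_params()].
#' @return An object of class `ost_bins`: a list with `bins` (named character
#'   vector, label -> concatenated member windows), `n_windows` (per-bin
#'   window count), `labels` (the label stream `L`, one entry per window),
#'   `t`, `w`, `k`.
#' @examples
#' b <- bin_text("AAAATTTTAAAA", codec_params(w = 4, k = 1, backend = "identity"))
#' b$bins
#' b$labels
#' @export
bin_text <- function(text, params) {
  stopifnot(inherits(params, "ost_params"))
  w <- params$w
  counts <- .window_count_matrix(text, w, params$alphabet)
  labels <- .labels_from_counts(counts, params$k, params$alphabet)
  windows <- split_windows(text, w)
  f <- factor(labels, levels = unique(labels))
  bins <- vapply(split(windows, f), paste, character(1L), collapse = "")
  structure(list(bins = bins,
                 n_windows = as.integer(table(f)[levels(f)]),
                 labels = labels,
                 t = nchar(text), w = w, k = params$k),
            class = "ost_bins")
}

#' @export
print.ost_bins <- function(x, ...) {
  cat(sprintf("OST binning: %d bases, %d windows (w = %d, k = %d), %d bins\n",
              x$t, length(x$labels), x$w, x$k, length(x$bins)))
  invisible(x)
}

#' Reassemble a genome from decoded bins and the label stream
#'
#' The inverse of [bin_text()]: a read cursor is kept per bin; for each label
#' in `L`, the next window (length `w`, or `t mod w` for a shorter final
#' window) is taken from that bin and appended. Consumes every bin exactly;
#' a bin that runs out early or has bytes left over signals corruption.
#'
#' @param decoded_bins Named character vector, label -> bin content, in the
#'   bin table's first-appearance order.
#' @param labels The label stream `L` (one label per window, window order).
#' @param w Window length used at compression.
#' @param t Original text length.
#' @return The reassembled genome text.
#' @export
unbin <- function(decoded_bins, labels, w, t) {
  w <- as.integer(w)
  t <- as.numeric(t)
  n <- length(labels)
  if (n != ceiling(t / w))
    stop(sprintf("label stream has %d entries; expected %d for t = %.0f, w = %d",
                 n, ceiling(t / w), t, w))
  if (sum(nchar(decoded_bins)) != t)
    stop(sprintf("decoded bins hold %.0f bases; expected t = %.0f",
                 sum(nchar(decoded_bins)), t))
  idx <- match(labels, names(decoded_bins))
  if (anyNA(idx)) {
    bad <- labels[which(is.na(idx))[1L]]
    stop(sprintf("label '%s' in L has no bin", bad))
  }
  unref <- setdiff(seq_along(decoded_bins), unique(idx))
  if (length(unref))
    stop(sprintf("corrupt archive: bin '%s' is never referenced by L",
                 names(decoded_bins)[unref[1L]]))
  len <- rep.int(w, n)
  if (t %% w != 0) len[n] <- as.integer(t %% w)
  ends <- stats::ave(len, idx, FUN = cumsum)
  starts <- ends - len + 1L
  # cursor overrun / leftover checks, per bin
  consumed <- vapply(split(ends, idx), max, numeric(1L))
  avail <- nchar(decoded_bins)[as.integer(names(consumed))]
  if (any(consumed > avail)) {
    b <- which(consumed > avail)[1L]
    stop(sprintf("corrupt archive: bin '%s' exhausted early (needs %.0f bases, has %d)",
                 names(decoded_bins)[as.integer(names(consumed))[b]],
                 consumed[b], avail[b]))
  }
  if (any(consumed < avail)) {
    b <- which(consumed < avail)[1L]
    stop(sprintf("corrupt archive: bin '%s' has %.0f leftover bases",
                 names(decoded_bins)[as.integer(names(consumed))[b]],
                 avail[b] - consumed[b]))
  }
  pieces <- substring(decoded_bins[idx], starts, ends)
  paste(pieces, collapse = "")
}
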