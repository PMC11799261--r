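# The single-file archive: header, entropy-coded label stream L, one
# compressed blob per bin, optional sidecar, all in a fixed little-endian
# byte layout.
#
# Layout (version 1):
#   magic "OST1" | u8 version | u8 k | u32 w | u8 backend id
#   | u8 alphabet length + alphabet bytes | u64 t | 32-byte SHA-256 of T
#   | u32 bin count
#   | label dictionary: u32 count; per label u16 byte length + label bytes
#     + u8 code length
#   | u64 L entry count | u32 payload byte length + payload
#   | per bin, in dictionary order: u32 label id + u64 blob length + blob
#   | u32 sidecar byte length (0 when absent) + sidecar bytes
# All integers little-endian. The L payload packs each code MSB-first and
# the concatenated bit string LSB-first into bytes, zero-padded to a byte
# boundary.

ARCHIVE_MAGIC <- charToRaw("OST1")
ARCHIVE_VERSION <- 1L

# ---- little-endian integer plumbing -----------------------------------

.uint_le <- function(x, nbytes) {
  x <- as.numeric(x)
  if (is.na(x) || x < 0) stop("cannot encode negative integer")
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- floor(x / 256)
  }
  if (x != 0) stop("integer too large for field width")
  out
}

.raw_reader <- function(bytes) {
  pos <- 0L
  n <- length(bytes)
  take <- function(k) {
    if (pos + k > n) stop("corrupt archive: truncated", call. = FALSE)
    out <- bytes[(pos + 1L):(pos + k)]
    pos <<- pos + as.integer(k)
    out
  }
  uint <- function(k) sum(as.numeric(take(k)) * 256^(seq_len(k) - 1))
  list(bytes = take,
       u8  = function() as.integer(uint(1L)),
       u16 = function() as.integer(uint(2L)),
       u32 = function() uint(4L),
       u64 = function() uint(8L),
       remaining = function() n - pos)
}

# ---- label stream coding ----------------------------------------------

# canonical codes (numeric, exact below 2^53) for given lengths; order by
# (length asc, id asc)
.canonical_codes <- function(lengths) {
  ord <- order(lengths, seq_along(lengths), method = "radix")
  codes <- numeric(length(lengths))
  prev_len <- lengths[ord[1L]]
  code <- 0
  for (i in seq_along(ord)) {
    l <- lengths[ord[i]]
    if (i > 1L) code <- (code + 1) * 2^(l - prev_len)
    codes[ord[i]] <- code
    prev_len <- l
  }
  codes
}

.code_bits <- function(code, len) {
  as.integer(floor(code / 2^((len - 1L):0)) %% 2)
}

#' Entropy-code a label stream
#'
#' Labels are mapped to integer ids in order of first appearance and coded
#' with a canonical Huffman code over their frequencies in `L`, so the label
#' of a larger bin — necessarily more frequent in `L` — gets a shorter code.
#' With a single distinct label the payload is empty and only the entry
#' count is stored.
#'
#' @param labels Character vector: the per-window label stream `L`.
#' @return An object of class `ost_elabels`: list with `dict` (labels in
#'   first-appearance order), `lengths` (per-label code length; 0 in the
#'   single-label case), `n` (entry count), `payload` (raw, bit-packed).
#' @export
encode_label_stream <- function(labels) {
  if (length(labels) == 0L) stop("empty label stream")
  dict <- unique(labels)
  ids <- match(labels, dict)
  n <- length(labels)
  if (length(dict) == 1L) {
    return(structure(list(dict = dict, lengths = 0L, n = n, payload = raw(0)),
                     class = "ost_elabels"))
  }
  freq <- tabulate(ids, nbins = length(dict))
  lens <- .huffman_lengths(freq)   # leaf creation order = first-appearance id
  codes <- .canonical_codes(lens)
  bitlist <- lapply(seq_along(dict), function(i) .code_bits(codes[i], lens[i]))
  bits <- unlist(bitlist[ids], use.names = FALSE)
  pad <- (-length(bits)) %% 8L
  if (pad) bits <- c(bits, integer(pad))
  structure(list(dict = dict, lengths = as.integer(lens), n = n,
                 payload = packBits(bits, type = "raw")),
            class = "ost_elabels")
}

#' Decode an entropy-coded label stream
#'
#' Exact inverse of [encode_label_stream()]. The canonical codes are
#' reconstructed from the stored per-label code lengths; a truncated payload
#' or an impossible code raises a corruption error.
#'
#' @param e An `ost_elabels` object.
#' @return Character vector of `e$n` labels.
#' @export
decode_label_stream <- function(e) {
  if (length(e$dict) == 1L) return(rep.int(e$dict, e$n))
  lens <- e$lengths
  ord <- order(lens, seq_along(lens), method = "radix")
  codes <- .canonical_codes(lens)
  maxlen <- max(lens)
  has_len <- logical(maxlen); first_code <- numeric(maxlen)
  count <- integer(maxlen); base <- integer(maxlen)
  sorted_lens <- lens[ord]
  for (l in unique(sorted_lens)) {
    sel <- which(sorted_lens == l)
    has_len[l] <- TRUE
    base[l] <- sel[1L]
    count[l] <- length(sel)
    first_code[l] <- codes[ord[sel[1L]]]
  }
  bits <- as.integer(rawToBits(e$payload))
  nbits <- length(bits)
  out <- integer(e$n)
  pos <- 1L
  for (i in seq_len(e$n)) {
    code <- 0
    l <- 0L
    repeat {
      if (l >= maxlen) stop("corrupt archive: invalid label code", call. = FALSE)
      if (pos > nbits) stop("corrupt archive: label payload truncated", call. = FALSE)
      code <- code * 2 + bits[pos]
      pos <- pos + 1L
      l <- l + 1L
      if (has_len[l]) {
        off <- code - first_code[l]
        if (off >= 0 && off < count[l]) {
          out[i] <- ord[base[l] + off]
          break
        }
      }
    }
  }
  rem <- nbits - pos + 1L
  if (rem >= 8L || (rem > 0L && any(bits[pos:nbits] == 1L)))
    stop("corrupt archive: trailing bits after label payload", call. = FALSE)
  e$dict[out]
}

# ---- archive serialization --------------------------------------------

#' Serialize an archive
#'
#' Deterministic byte layout (see the package source header of this file for
#' the field-by-field description): identical inputs yield identical bytes.
#'
#' @param params [codec_params()] used for compression.
#' @param labels Label stream `L`.
#' @param blobs List of raw vectors: per-bin compressed bytes, in the label
#'   dictionary's first-appearance order.
#' @param t Original text length.
#' @param checksum 32-byte raw SHA-256 of the original text.
#' @param sidecar Optional raw vector of compressed sidecar metadata.
#' @return Raw vector: the archive bytes.
#' @export
write_archive <- function(params, labels, blobs, t, checksum, sidecar = NULL) {
  stopifnot(inherits(params, "ost_params"))
  if (length(checksum) != 32L || !is.raw(checksum))
    stop("checksum must be a 32-byte raw vector")
  e <- encode_label_stream(labels)
  if (length(blobs) != length(e$dict))
    stop(sprintf("blob count (%d) does not match bin count (%d)",
                 length(blobs), length(e$dict)))
  alphabet <- paste(params$alphabet, collapse = "")
  dict_parts <- lapply(seq_along(e$dict), function(i) {
    lab <- charToRaw(e$dict[i])
    c(.uint_le(length(lab), 2L), lab, .uint_le(e$lengths[i], 1L))
  })
  bin_parts <- lapply(seq_along(blobs), function(i) {
    c(.uint_le(i - 1L, 4L), .uint_le(length(blobs[[i]]), 8L), blobs[[i]])
  })
  if (is.null(sidecar)) sidecar <- raw(0)
  c(ARCHIVE_MAGIC,
    .uint_le(ARCHIVE_VERSION, 1L),
    .uint_le(params$k, 1L),
    .uint_le(params$w, 4L),
    .uint_le(.backend(params$backend)$id, 1L),
    .uint_le(nchar(alphabet), 1L), charToRaw(alphabet),
    .uint_le(t, 8L),
    checksum,
    .uint_le(length(blobs), 4L),
    .uint_le(length(e$dict), 4L), do.call(c, dict_parts),
    .uint_le(e$n, 8L),
    .uint_le(length(e$payload), 4L), e$payload,
    do.call(c, bin_parts),
    .uint_le(length(sidecar), 4L), sidecar)
}

#' Parse an archive
#'
#' Validates magic, version, field consistency, and completeness of the byte
#' stream. The text checksum is verified later, by [decompress_text()],
#' once the bins have been decompressed.
#'
#' @param bytes Raw vector: archive bytes.
#' @return List with `header` (list of the header fields), `labels` (decoded
#'   label stream), `blobs` (named list of raw vectors, dictionary order),
#'   and `sidecar` (raw vector or `NULL`).
#' @export
read_archive <- function(bytes) {
  if (!is.raw(bytes)) stop("archive must be a raw vector")
  if (length(bytes) < 4L || !identical(bytes[1:4], ARCHIVE_MAGIC))
    stop("bad magic: not an OST archive")
  r <- .raw_reader(bytes)
  r$bytes(4L)
  version <- r$u8()
  if (version != ARCHIVE_VERSION)
    stop(sprintf("unsupported archive version %d", version))
  k <- r$u8()
  w <- as.integer(r$u32())
  backend_id <- r$u8()
  alen <- r$u8()
  alphabet <- strsplit(rawToChar(r$bytes(alen)), "", fixed = TRUE)[[1L]]
  t <- r$u64()
  checksum <- r$bytes(32L)
  n_bins <- r$u32()
  dict_n <- r$u32()
  if (dict_n != n_bins)
    stop("corrupt archive: bin count does not match label dictionary size")
  dict <- character(dict_n)
  lens <- integer(dict_n)
  for (i in seq_len(dict_n)) {
    ll <- r$u16()
    dict[i] <- rawToChar(r$bytes(ll))
    lens[i] <- r$u8()
  }
  n_entries <- r$u64()
  payload <- r$bytes(r$u32())
  e <- structure(list(dict = dict, lengths = lens, n = n_entries,
                      payload = payload),
                 class = "ost_elabels")
  labels <- decode_label_stream(e)
  blobs <- vector("list", n_bins)
  for (i in seq_len(n_bins)) {
    id <- r$u32()
    if (id != i - 1L)
      stop("corrupt archive: bin blobs out of dictionary order")
    blobs[[i]] <- r$bytes(r$u64())
  }
  names(blobs) <- dict
  sc_len <- r$u32()
  sidecar <- if (sc_len > 0) r$bytes(sc_len) else NULL
  if (r$remaining() != 0L)
    stop("corrupt archive: trailing bytes")
  list(header = list(version = version, w = w, k = k,
                     backend = .backend_name_from_id(backend_id),
                     alphabet = alphabet, t = t, checksum = checksum,
                     n_bins = as.integer(n_bins)),
       labels = labels, blobs = blobs, sidecar = sidecar)
}

# ---- end-to-end text codec --------------------------------------------

.sha256_raw <- function(text) {
  digest::digest(charToRaw(text), algo = "sha256", serialize = FALSE,
                 raw = TRUE)
}

#' Compress a one-line genome into an archive
#'
#' Full forward pipeline: [bin_text()], independent backend compression of
#' each bin's concatenated content, entropy coding of the label stream, and
#' archive serialization with a SHA-256 of the input for end-to-end
#' verification.
#'
#' @param text One-line genome over the alphabet in `params`.
#' @param params [codec_params()].
#' @param sidecar Optional raw vector stored verbatim in the archive's
#'   sidecar block (used by the lossless FASTA mode).
#' @return Raw vector: the archive.
#' @examples
#' a <- compress_text("ACGTACGTAAAAAAAA", codec_params(w = 4, k = 2,
#'                    backend = "identity"))
#' decompress_text(a)
#' @export
compress_text <- function(text, params, sidecar = NULL) {
  text <- as.character(text)   # drop any attributes (e.g. generator metadata)
  b <- bin_text(text, params)
  blobs <- lapply(unname(b$bins), function(content)
    compress_blob(params$backend, charToRaw(content)))
  write_archive(params, b$labels, blobs, b$t, .sha256_raw(text),
                sidecar = sidecar)
}

#' Decompress an archive back to the original genome
#'
#' Inverse pipeline: parse, per-bin backend decompression, cursor-based
#' window reassembly via the label stream, and SHA-256 verification against
#' the checksum stored at compression time.
#'
#' @param bytes Raw vector: archive bytes.
#' @return The original text. If the archive carries a sidecar block it is
#'   attached as the `"sidecar"` attribute (raw vector).
#' @export
decompress_text <- function(bytes) {
  a <- read_archive(bytes)
  backend <- a$header$backend
  decoded <- vapply(a$blobs, function(blob)
    rawToChar(decompress_blob(backend, blob)), character(1L))
  text <- unbin(decoded, a$labels, a$header$w, a$header$t)
  if (!identical(.sha256_raw(text), a$header$checksum))
    stop("corrupt archive: checksum mismatch after decompression")
  if (!is.null(a$sidecar)) attr(text, "sidecar") <- a$sidecar
  text
}
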