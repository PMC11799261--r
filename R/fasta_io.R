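# FASTA reading/writing plus the two preprocessing modes:
#   * paper mode  — destructive one-line text: newlines, headers, lowercase
#     (soft-masked) bases and non-ACGTN characters are removed;
#   * lossless mode — the same one-line text, but every discarded detail
#     (headers, line lengths, case intervals, dropped characters) is kept in
#     sidecar metadata so the original file is restored byte-for-byte.

#' Read a FASTA file preserving its exact byte structure
#'
#' Unlike sequence-oriented readers, this parser keeps everything needed to
#' reconstruct the file byte-for-byte: header lines verbatim, sequence lines
#' as stored (case, width, stray characters), and whether the file ends with
#' a newline.
#'
#' @param path Path to a FASTA file, or `NULL` when `text` is given.
#' @param text A single string of FASTA content (alternative to `path`).
#' @param strict If `TRUE` (default), sequence data before the first header
#'   is an error; if `FALSE` it becomes a record with header `NA`.
#' @return An object of class `ost_fasta`: list with `records` (each a list
#'   with `header`, a string without the leading `>`, or `NA`, and `lines`,
#'   a character vector of sequence lines) and `trailing_newline` (logical).
#' @export
read_fasta <- function(path = NULL, text = NULL, strict = TRUE) {
  if (is.null(text)) {
    raw <- readBin(path, what = "raw", n = file.info(path)$size)
    text <- rawToChar(raw)
  }
  trailing <- nchar(text) > 0L && substr(text, nchar(text), nchar(text)) == "\n"
  body <- if (trailing) substr(text, 1L, nchar(text) - 1L) else text
  records <- list()
  if (nchar(body) > 0L || trailing) {
    lines <- strsplit(body, "\n", fixed = TRUE)[[1L]]
    # strsplit drops a trailing empty field: "a\n" -> "a"; restore explicit
    # empty final line when body ends with "\n"
    if (nchar(body) > 0L && substr(body, nchar(body), nchar(body)) == "\n")
      lines <- c(lines, "")
    if (length(lines) == 0L) lines <- ""
    is_header <- startsWith(lines, ">")
    if (!is_header[1L]) {
      if (strict) stop("sequence data before the first FASTA header")
      grp <- cumsum(is_header)          # leading group 0: headerless record
    } else {
      grp <- cumsum(is_header)
    }
    for (g in unique(grp)) {
      chunk <- lines[grp == g]
      if (g == 0L) {
        records[[length(records) + 1L]] <- list(header = NA_character_,
                                                lines = chunk)
      } else {
        records[[length(records) + 1L]] <-
          list(header = substr(chunk[1L], 2L, nchar(chunk[1L])),
               lines = chunk[-1L])
      }
    }
  }
  structure(list(records = records, trailing_newline = trailing),
            class = "ost_fasta")
}

#' Write an `ost_fasta` object back to text
#'
#' Exact inverse of [read_fasta()]: reproduces the original bytes.
#'
#' @param fa An `ost_fasta` object.
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The FASTA text (invisibly when written to `path`).
#' @export
write_fasta <- function(fa, path = NULL) {
  stopifnot(inherits(fa, "ost_fasta"))
  chunks <- vapply(fa$records, function(rec) {
    lines <- if (is.na(rec$header)) rec$lines
             else c(paste0(">", rec$header), rec$lines)
    paste(lines, collapse = "\n")
  }, character(1L))
  out <- paste(chunks, collapse = "\n")
  if (fa$trailing_newline) out <- paste0(out, "\n")
  if (!is.null(path)) {
    writeBin(charToRaw(out), path)
    return(invisible(out))
  }
  out
}

.seq_text <- function(fa) {
  paste(unlist(lapply(fa$records, `[[`, "lines"), use.names = FALSE),
        collapse = "")
}

#' Destructive one-line preprocessing
#'
#' Concatenates all sequence lines of all records and deletes every character
#' that is not an uppercase A, C, G, T or N — newlines, headers, lowercase
#' (soft-masked) bases, and any other character are removed, not converted.
#' The result is the "one-line genome" the codec and the benchmark operate
#' on. This mode is irreversible by construction; use [lossless_flatten()]
#' when the original file must be restorable.
#'
#' @param fa An `ost_fasta` object.
#' @return A single string over `{A,C,G,T,N}` (possibly empty).
#' @export
paper_preprocess <- function(fa) {
  stopifnot(inherits(fa, "ost_fasta"))
  gsub("[^ACGTN]", "", .seq_text(fa), perl = TRUE)
}

#' Lossless flattening with sidecar metadata
#'
#' Produces the same one-line uppercase text a compressor wants, while
#' recording everything needed to reverse it: record headers, per-record
#' line lengths, lowercase (soft-mask) runs as zero-based half-open
#' intervals in final-text coordinates, and non-ACGTN characters as
#' (insertion position, character) pairs, also in final-text coordinates.
#' [restore_fasta()] inverts it byte-exactly.
#'
#' @param fa An `ost_fasta` object.
#' @return List with `text` (the one-line genome) and `meta` (an
#'   `ost_sidecar` object).
#' @export
lossless_flatten <- function(fa) {
  stopifnot(inherits(fa, "ost_fasta"))
  s <- .seq_text(fa)
  headers <- vapply(fa$records, `[[`, character(1L), "header")
  line_lengths <- lapply(fa$records, function(rec) nchar(rec$lines))
  if (nchar(s) == 0L) {
    meta <- structure(list(headers = headers, line_lengths = line_lengths,
                           case_start = integer(0), case_end = integer(0),
                           dropped_pos = integer(0),
                           dropped_chars = character(0),
                           trailing_newline = fa$trailing_newline),
                      class = "ost_sidecar")
    return(list(text = "", meta = meta))
  }
  orig <- charToRaw(s)
  up <- charToRaw(toupper(s))
  is_dna <- logical(256L)
  is_dna[as.integer(charToRaw("ACGTN")) + 1L] <- TRUE
  keep <- is_dna[as.integer(up) + 1L]
  kept_before <- cumsum(keep)                      # kept chars up to position
  lower_kept <- which(keep & (orig != up))
  case_pos <- kept_before[lower_kept] - 1L         # zero-based, final coords
  if (length(case_pos)) {
    brk <- c(TRUE, diff(case_pos) != 1L)
    case_start <- case_pos[brk]
    case_end <- case_pos[c(brk[-1L], TRUE)] + 1L   # half-open
  } else {
    case_start <- case_end <- integer(0)
  }
  drop_idx <- which(!keep)
  dropped_pos <- kept_before[drop_idx]             # zero-based insertion index
  dropped_chars <- if (length(drop_idx))
    substring(s, drop_idx, drop_idx) else character(0)
  meta <- structure(list(headers = headers, line_lengths = line_lengths,
                         case_start = as.integer(case_start),
                         case_end = as.integer(case_end),
                         dropped_pos = as.integer(dropped_pos),
                         dropped_chars = dropped_chars,
                         trailing_newline = fa$trailing_newline),
                    class = "ost_sidecar")
  list(text = rawToChar(up[keep]), meta = meta)
}

#' Restore the original FASTA bytes from flattened text plus sidecar
#'
#' Re-applies the lowercase mask, re-inserts dropped characters (right to
#' left, so earlier insertion positions stay valid), re-wraps the sequence
#' into its original line lengths, and reattaches headers and the trailing
#' newline.
#'
#' @param text One-line genome from [lossless_flatten()].
#' @param meta The matching `ost_sidecar`.
#' @return The original FASTA text, byte-exact.
#' @export
restore_fasta <- function(text, meta) {
  stopifnot(inherits(meta, "ost_sidecar"))
  r <- charToRaw(text)
  if (length(meta$case_start)) {
    pos <- unlist(mapply(function(a, b) seq.int(a, b - 1L),
                         meta$case_start, meta$case_end, SIMPLIFY = FALSE),
                  use.names = FALSE)
    if (length(pos) && (any(pos < 0) || any(pos >= length(r))))
      stop("inconsistent metadata: case interval outside sequence bounds")
    r[pos + 1L] <- as.raw(as.integer(r[pos + 1L]) + 32L)  # ASCII lowercase
  }
  seqtext <- rawToChar(r)
  m <- length(meta$dropped_pos)
  if (m) {
    p <- meta$dropped_pos
    if (any(p < 0) || any(p > nchar(seqtext)) || is.unsorted(p))
      stop("inconsistent metadata: dropped-character positions invalid")
    segs <- substring(seqtext, c(0L, p) + 1L, c(p, nchar(seqtext)))
    v <- character(2L * m + 1L)
    v[seq(1L, 2L * m + 1L, by = 2L)] <- segs
    v[seq(2L, 2L * m, by = 2L)] <- meta$dropped_chars
    seqtext <- paste(v, collapse = "")
  }
  all_lens <- unlist(meta$line_lengths, use.names = FALSE)
  if (sum(all_lens) != nchar(seqtext))
    stop("inconsistent metadata: line lengths do not match sequence length")
  ends <- cumsum(all_lens)
  lines <- if (length(all_lens))
    substring(seqtext, ends - all_lens + 1L, ends) else character(0)
  counts <- lengths(meta$line_lengths)
  grp <- rep.int(seq_along(counts), counts)
  records <- lapply(seq_along(meta$headers), function(i)
    list(header = meta$headers[i], lines = lines[grp == i]))
  write_fasta(structure(list(records = records,
                             trailing_newline = meta$trailing_newline),
                        class = "ost_fasta"))
}

# ---- sidecar (de)serialization ----------------------------------------

# JSON chosen for transparency; the blob is backend-compressed inside the
# archive so verbosity is cheap.
.sidecar_to_raw <- function(meta, mode = "lossless", extra = list()) {
  payload <- c(list(mode = mode), extra)
  if (!is.null(meta)) {
    payload$headers <- lapply(meta$headers,
                              function(h) if (is.na(h)) NULL else h)
    payload$line_lengths <- lapply(meta$line_lengths, as.integer)
    payload$case_start <- meta$case_start
    payload$case_end <- meta$case_end
    payload$dropped_pos <- meta$dropped_pos
    payload$dropped_chars <- meta$dropped_chars
    payload$trailing_newline <- meta$trailing_newline
  }
  charToRaw(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                          null = "null", digits = NA)))
}

.sidecar_from_raw <- function(bytes) {
  x <- jsonlite::fromJSON(rawToChar(bytes), simplifyVector = FALSE)
  if (is.null(x$mode)) stop("corrupt sidecar: no mode")
  if (x$mode != "lossless") return(list(mode = x$mode, extra = x))
  meta <- structure(list(
    headers = vapply(x$headers,
                     function(h) if (is.null(h)) NA_character_ else h,
                     character(1L)),
    line_lengths = lapply(x$line_lengths,
                          function(v) as.integer(unlist(v, use.names = FALSE))),
    case_start = as.integer(unlist(x$case_start, use.names = FALSE)),
    case_end = as.integer(unlist(x$case_end, use.names = FALSE)),
    dropped_pos = as.integer(unlist(x$dropped_pos, use.names = FALSE)),
    dropped_chars = as.character(unlist(x$dropped_chars, use.names = FALSE)),
    trailing_newline = isTRUE(x$trailing_newline)),
    class = "ost_sidecar")
  list(mode = "lossless", meta = meta)
}
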