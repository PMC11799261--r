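# Benchmark harness: compression-ratio accounting, the window x label grid
# sweep, and head-to-head comparison against the standalone backend.

#' Compression ratio in percent
#'
#' Defined as compressed size divided by original size, times 100 — lower is
#' better.
#'
#' @param original Original size in bytes (> 0).
#' @param compressed Compressed size in bytes.
#' @return Percent ratio.
#' @export
compression_ratio <- function(original, compressed) {
  if (!is.numeric(original) || length(original) != 1L || is.na(original) ||
      original <= 0)
    stop("original size must be a positive number")
  100 * as.numeric(compressed) / as.numeric(original)
}

# one-row report; MB here means 10^6 bytes
.ratio_report <- function(original, compressed, comp_s = NA_real_,
                          decomp_s = NA_real_) {
  data.frame(original_bytes = as.numeric(original),
             compressed_bytes = as.numeric(compressed),
             ratio_pct = compression_ratio(original, compressed),
             saved_mb = (as.numeric(original) - as.numeric(compressed)) / 1e6,
             comp_s = comp_s, decomp_s = decomp_s,
             comp_mb_s = as.numeric(original) / 1e6 / comp_s,
             decomp_mb_s = as.numeric(original) / 1e6 / decomp_s)
}

.timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Compare the codec against its standalone backend
#'
#' Compresses the text twice — through the full classify-and-bin pipeline,
#' and as a single blob with the bare backend — verifies both paths are
#' lossless, and reports both ratio rows plus the saving delta. Timings are
#' recorded for context; they are hardware-dependent and never asserted.
#'
#' @param text One-line genome.
#' @param params [codec_params()].
#' @return List with `ost` and `baseline` (one-row ratio reports) and
#'   `delta_saved_mb` = baseline compressed bytes − archive bytes, in MB
#'   (positive when binning wins).
#' @export
compare_vs_standalone <- function(text, params) {
  text <- as.character(text)
  t <- nchar(text)
  ct <- .timed(compress_text(text, params))
  dt <- .timed(decompress_text(ct$value))
  if (!identical(as.character(dt$value), text))
    stop("internal error: archive round trip failed verification")
  cb <- .timed(compress_blob(params$backend, charToRaw(text)))
  db <- .timed(decompress_blob(params$backend, cb$value))
  if (!identical(rawToChar(db$value), text))
    stop("internal error: baseline round trip failed verification")
  ost <- .ratio_report(t, length(ct$value), ct$elapsed, dt$elapsed)
  baseline <- .ratio_report(t, length(cb$value), cb$elapsed, db$elapsed)
  list(ost = ost, baseline = baseline,
       delta_saved_mb = (length(cb$value) - length(ct$value)) / 1e6)
}

#' Sweep the window-length x label-length grid
#'
#' Runs the codec once per `(w, k)` cell plus one standalone-backend
#' baseline row, verifying every run losslessly round-trips before its ratio
#' is recorded. `binsonly_bytes` counts the compressed bin blobs alone
#' (comparable to compressing bins as separate files, without the archive's
#' header and label stream); `compressed_bytes` is the honest single-file
#' archive size.
#'
#' @param text One-line genome.
#' @param windows Window lengths to sweep. The genome-scale reference grid
#'   is `c(25, 50, 100, 125, 150, 250, 500, 750, 1000, 2500, 5000, 10000)`.
#' @param labels Label lengths to sweep (reference grid `1:5`).
#' @param backend Backend id.
#' @return A data frame with columns `w, k, bins, compressed_bytes,
#'   binsonly_bytes, ratio_pct, comp_s, decomp_s`; the final row (`w`, `k`
#'   both `NA`) is the standalone baseline. Attribute `"best"` holds the
#'   minimum-ratio OST row (ties to smaller `w`, then smaller `k`).
#' @export
sweep_grid <- function(text, windows, labels, backend = "bzip2") {
  if (length(windows) == 0L || length(labels) == 0L)
    stop("window and label grids must be non-empty")
  text <- as.character(text)
  t <- nchar(text)
  grid <- expand.grid(k = sort(as.integer(labels)),
                      w = sort(as.integer(windows)))[, c("w", "k")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- codec_params(w = grid$w[i], k = grid$k[i], backend = backend)
    ct <- .timed(compress_text(text, params))
    dt <- .timed(decompress_text(ct$value))
    if (!identical(as.character(dt$value), text))
      stop(sprintf("round-trip failure at w = %d, k = %d",
                   grid$w[i], grid$k[i]))
    a <- read_archive(ct$value)
    data.frame(w = grid$w[i], k = grid$k[i],
               bins = a$header$n_bins,
               compressed_bytes = length(ct$value),
               binsonly_bytes = sum(vapply(a$blobs, length, integer(1L))),
               ratio_pct = compression_ratio(t, length(ct$value)),
               comp_s = ct$elapsed, decomp_s = dt$elapsed)
  })
  cb <- .timed(compress_blob(backend, charToRaw(text)))
  db <- .timed(decompress_blob(backend, cb$value))
  if (!identical(rawToChar(db$value), text))
    stop("baseline round-trip failure")
  baseline <- data.frame(w = NA_integer_, k = NA_integer_, bins = NA_integer_,
                         compressed_bytes = length(cb$value),
                         binsonly_bytes = length(cb$value),
                         ratio_pct = compression_ratio(t, length(cb$value)),
                         comp_s = cb$elapsed, decomp_s = db$elapsed)
  out <- rbind(do.call(rbind, rows), baseline)
  rownames(out) <- NULL
  ost <- out[!is.na(out$w), ]
  best <- ost[order(ost$ratio_pct, ost$w, ost$k), ][1L, ]
  attr(out, "best") <- best
  out
}
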