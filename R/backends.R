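# Pluggable general-purpose codecs used to compress each bin independently.
# Numeric ids are frozen for archive compatibility:
#   0 = identity, 1 = deflate, 2 = bzip2, 3 = xz, 4 = zstd, 5 = brotli.
# Only formats available through base R's memCompress are registered; ids
# 4 and 5 are reserved for optional plugins.

.backend_registry <- list(
  identity = list(
    id = 0L,
    compress   = function(data) data,
    decompress = function(data) data
  ),
  deflate = list(
    id = 1L,
    compress   = function(data) memCompress(data, type = "gzip"),
    decompress = function(data) memDecompress(data, type = "gzip")
  ),
  bzip2 = list(
    id = 2L,
    compress   = function(data) memCompress(data, type = "bzip2"),
    decompress = function(data) memDecompress(data, type = "bzip2")
  ),
  xz = list(
    id = 3L,
    compress   = function(data) memCompress(data, type = "xz"),
    decompress = function(data) memDecompress(data, type = "xz")
  )
)

.backend <- function(backend) {
  b <- .backend_registry[[backend]]
  if (is.null(b)) stop(sprintf("unknown backend '%s'", backend))
  b
}

.backend_name_from_id <- function(id) {
  ids <- vapply(.backend_registry, `[[`, integer(1L), "id")
  nm <- names(ids)[match(as.integer(id), ids)]
  if (is.na(nm)) stop(sprintf("unknown backend id %d", as.integer(id)))
  nm
}

#' List registered backend codecs
#'
#' @return Character vector of backend ids usable in [codec_params()].
#'   Always contains `"identity"`; all backends run single-threaded with
#'   their library defaults.
#' @export
list_backends <- function() names(.backend_registry)

#' Compress a byte blob with a backend codec
#'
#' @param backend A backend id from [list_backends()].
#' @param data Raw vector.
#' @return Raw vector; [decompress_blob()] with the same backend inverts it
#'   exactly.
#' @export
compress_blob <- function(backend, data) {
  if (!is.raw(data)) stop("data must be a raw vector")
  .backend(backend)$compress(data)
}

#' Decompress a byte blob
#'
#' @inheritParams compress_blob
#' @return The original raw vector. Malformed input raises a corruption
#'   error.
#' @export
decompress_blob <- function(backend, data) {
  if (!is.raw(data)) stop("data must be a raw vector")
  b <- .backend(backend)
  tryCatch(b$decompress(data), error = function(e) {
    stop(sprintf("corrupt blob (%s backend): %s", backend,
                 conditionMessage(e)), call. = FALSE)
  })
}
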