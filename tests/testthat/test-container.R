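params_id <- function(w = 4, k = 2) codec_params(w = w, k = k,
                                                 backend = "identity")

test_that("label-stream coding handles the degenerate and two-symbol cases", {
  e1 <- encode_label_stream(rep("A_1", 7))
  expect_equal(e1$n, 7L)
  expect_length(e1$payload, 0L)
  expect_identical(decode_label_stream(e1), rep("A_1", 7))

  e2 <- encode_label_stream(c("a", "a", "a", "b"))
  expect_equal(e2$lengths, c(1L, 1L))   # both codes 1 bit
  expect_length(e2$payload, 1L)         # 4 bits padded to one byte
  expect_identical(decode_label_stream(e2), c("a", "a", "a", "b"))
})

test_that("label-stream coding is an exact inverse on random streams", {
  set.seed(606)
  for (i in 1:50) {
    n_lab <- sample(1:12, 1)
    L <- sample(paste0("lab", seq_len(n_lab)), sample(1:500, 1),
                replace = TRUE, prob = stats::runif(n_lab)^2 + 0.01)
    e <- encode_label_stream(L)
    expect_identical(decode_label_stream(e), L)
    # a strictly more frequent label never gets a longer code (equal
    # frequencies may legitimately differ in length)
    if (length(e$dict) >= 2) {
      f <- tabulate(match(L, e$dict), nbins = length(e$dict))
      uf <- sort(unique(f))
      mx <- vapply(uf, function(x) max(e$lengths[f == x]), integer(1L))
      mn <- vapply(uf, function(x) min(e$lengths[f == x]), integer(1L))
      if (length(uf) >= 2)
        expect_true(all(mn[-length(uf)] >= mx[-1]))
      expect_equal(sum(2^(-e$lengths)), 1)
    }
  }
})

test_that("truncated or corrupted label payloads raise corruption errors", {
  L <- sample(c("x", "y", "z"), 64, replace = TRUE, prob = c(.6, .3, .1))
  e <- encode_label_stream(L)
  trunc <- e
  trunc$payload <- trunc$payload[seq_len(length(trunc$payload) - 2L)]
  expect_error(decode_label_stream(trunc), "truncated")
  over <- e
  over$n <- over$n + 200L
  expect_error(decode_label_stream(over), "truncated|invalid")
})

test_that("archives start with the magic and round-trip all fields", {
  s <- "ACGTACGTAAAATTTTGGGG"
  a <- compress_text(s, params_id())
  expect_identical(a[1:4], charToRaw("OST1"))
  r <- read_archive(a)
  expect_equal(r$header$w, 4L)
  expect_equal(r$header$k, 2L)
  expect_equal(r$header$backend, "identity")
  expect_equal(r$header$t, 20)
  expect_equal(r$header$alphabet, c("A", "C", "G", "T", "N"))
  expect_equal(r$header$n_bins, length(r$blobs))
  expect_identical(decompress_text(a), s)
})

test_that("write_archive is deterministic and k changes exactly one header byte", {
  L <- c("a", "b", "a")
  blobs <- list(charToRaw("AAAA"), charToRaw("CCCC"))
  ck <- digest::digest(charToRaw("x"), algo = "sha256", serialize = FALSE,
                       raw = TRUE)
  a1 <- write_archive(params_id(k = 2), L, blobs, 12, ck)
  a2 <- write_archive(params_id(k = 2), L, blobs, 12, ck)
  expect_identical(a1, a2)
  a3 <- write_archive(params_id(k = 3), L, blobs, 12, ck)
  expect_equal(length(a1), length(a3))
  expect_equal(which(a1 != a3), 6L)   # magic(4) + version(1), then k
})

test_that("malformed archives fail with distinct diagnostics", {
  expect_error(read_archive(raw(0)), "bad magic")
  expect_error(read_archive(charToRaw("NOPE1234")), "bad magic")
  s <- random_dna(300)
  a <- compress_text(s, params_id(w = 25))
  expect_error(read_archive(a[1:40]), "truncated")
  bad_ver <- a; bad_ver[5] <- as.raw(9)
  expect_error(read_archive(bad_ver), "unsupported archive version")
  expect_error(read_archive(c(a, as.raw(0))), "trailing bytes")
})

test_that("a bit flip in a blob is caught at or before checksum verification", {
  set.seed(707)
  s <- random_dna(400)
  for (be in c("identity", "bzip2")) {
    a <- compress_text(s, codec_params(w = 25, k = 2, backend = be))
    # flip one bit inside the final blob region (before the sidecar length)
    pos <- length(a) - 10L
    a[pos] <- xor(a[pos], as.raw(1))
    expect_error(decompress_text(a), "corrupt|checksum|truncated")
  }
})

test_that("identity-backend archive size follows the layout accounting exactly", {
  s <- paste(rep("ACGTT", 200), collapse = "")  # 1000 bases
  p <- params_id(w = 25, k = 2)
  a <- compress_text(s, p)
  b <- bin_text(s, p)
  e <- encode_label_stream(b$labels)
  header <- 4 + 1 + 1 + 4 + 1 + 1 + 5 + 8 + 32 + 4
  dict <- 4 + sum(2 + nchar(e$dict) + 1)
  lstream <- 8 + 4 + length(e$payload)
  bins <- sum(4 + 8 + nchar(b$bins))   # identity: blob bytes == bin bytes
  sidecar <- 4
  expect_equal(length(a), header + dict + lstream + bins + sidecar)
})

test_that("a homogeneous genome yields one bin and an empty label payload", {
  a <- compress_text(strrep("A", 1000), params_id(w = 25, k = 3))
  r <- read_archive(a)
  expect_equal(r$header$n_bins, 1L)
  expect_equal(unique(r$labels), "A_1")
  expect_identical(decompress_text(a), strrep("A", 1000))
})

test_that("sidecar bytes survive the archive round trip", {
  sc <- charToRaw('{"mode":"raw","trailing_newline":true}')
  a <- compress_text("ACGTACGT", params_id(), sidecar = sc)
  out <- decompress_text(a)
  expect_identical(attr(out, "sidecar"), sc)
  expect_identical(as.character(out), "ACGTACGT")
})
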