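test_that("split_windows cuts non-overlapping windows whose concatenation is the input", {
  expect_equal(nchar(split_windows(strrep("A", 10), 4)), c(4L, 4L, 2L))
  expect_equal(nchar(split_windows(strrep("A", 8), 4)), c(4L, 4L))
  expect_equal(split_windows("ACG", 100), "ACG")
  expect_error(split_windows("", 4), "empty text")
  s <- random_dna(137)
  expect_identical(paste(split_windows(s, 10), collapse = ""), s)
})

test_that("bin_text matches the hand-traced examples", {
  b <- bin_text("AAAATTTTAAAA", codec_params(w = 4, k = 5, backend = "identity"))
  expect_equal(b$bins, c(A_1 = "AAAAAAAA", T_1 = "TTTT"))
  expect_equal(b$n_windows, c(2L, 1L))
  expect_equal(b$labels, c("A_1", "T_1", "A_1"))

  b2 <- bin_text("ACGTACGT", codec_params(w = 4, k = 4, backend = "identity"))
  expect_equal(names(b2$bins), "ACGT_2222")
  expect_equal(b2$labels, rep("ACGT_2222", 2))

  # w >= t: a single window, single bin
  b3 <- bin_text("ACG", codec_params(w = 100, k = 2, backend = "identity"))
  expect_length(b3$labels, 1L)
  expect_length(b3$bins, 1L)
})

test_that("bin_text names the offending window on out-of-alphabet input", {
  expect_error(
    bin_text("ACGTACGX", codec_params(w = 4, k = 1, backend = "identity")),
    "'X' at offset 7 \\(window 2\\)")
})

test_that("unbin inverts bin_text across random texts, window and label lengths", {
  set.seed(404)
  for (i in 1:60) {
    t_len <- sample(1:2000, 1)
    s <- random_dna(t_len)
    w <- sample(c(1L, 2L, 3L, 5L, 25L, 250L), 1)
    k <- sample(1:5, 1)
    b <- bin_text(s, codec_params(w = w, k = k, backend = "identity"))
    expect_identical(unbin(b$bins, b$labels, w, t_len), s)
    # conservation
    expect_equal(sum(nchar(b$bins)), t_len)
    expect_length(b$labels, ceiling(t_len / w))
    # every window in a bin re-labels to the bin's label
    expect_true(all(b$labels %in% names(b$bins)))
  }
})

test_that("bin count is non-decreasing in label length k", {
  set.seed(505)
  s <- random_dna(5000, prob = c(.4, .25, .2, .1, .05))
  for (w in c(5L, 25L, 100L)) {
    n_bins <- vapply(1:5, function(k)
      length(bin_text(s, codec_params(w = w, k = k,
                                      backend = "identity"))$bins),
      integer(1L))
    expect_true(all(diff(n_bins) >= 0))
  }
})

test_that("unbin detects tampering and inconsistent inputs", {
  s <- "AAAATTTTAAAACCCC"
  b <- bin_text(s, codec_params(w = 4, k = 1, backend = "identity"))
  # swapping two different labels misaligns bin cursors
  L2 <- b$labels
  i <- which(L2 == "T_1")[1]; j <- which(L2 == "C_1")[1]
  L2[c(i, j)] <- L2[c(j, i)]
  out <- unbin(b$bins, L2, 4, nchar(s))
  expect_false(identical(out, s))   # checksum catches this downstream
  # total length mismatch is caught up front
  short <- b$bins; short[["A_1"]] <- "AAAA"
  expect_error(unbin(short, b$labels, 4, nchar(s)), "bases; expected t")
  # same total but misallocated: one bin runs dry, another has leftovers
  skew <- c(A_1 = "AAAA", T_1 = "TTTTTTTT", C_1 = "CCCC")
  expect_error(unbin(skew, b$labels, 4, nchar(s)), "exhausted early")
  # wrong label stream length
  expect_error(unbin(b$bins, b$labels[-1], 4, nchar(s)), "expected")
})

test_that("windows processed equals ceil(t/w) for partial final windows", {
  s <- random_dna(1001)
  b <- bin_text(s, codec_params(w = 250, k = 2, backend = "identity"))
  expect_length(b$labels, 5L)
  expect_identical(unbin(b$bins, b$labels, 250, 1001), s)
})
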