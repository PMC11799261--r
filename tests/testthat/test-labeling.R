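test_that("count_symbols reports exact multiplicities and locates bad characters", {
  expect_equal(count_symbols("GGGGA"),
               c(A = 1L, C = 0L, G = 4L, T = 0L, N = 0L))
  expect_equal(sum(count_symbols("GGGGA")), 5L)
  expect_equal(count_symbols("ACGTN"),
               c(A = 1L, C = 1L, G = 1L, T = 1L, N = 1L))
  expect_error(count_symbols(""), "empty window")
  expect_error(count_symbols("ACGX"), "'X' at offset 3")
})

test_that("the worked Huffman schema labels as GATC_1233 / GA_12 / G_1", {
  # window whose optimal code is G: 1 bit, A: 2, T: 3, C: 3, with
  # freq(T) >= freq(C)
  ft <- count_symbols(paste0(strrep("G", 8), strrep("A", 4),
                             strrep("T", 2), "C"))
  cla <- assign_code_lengths(ft)
  expect_equal(cla, c(A = 2L, C = 3L, G = 1L, T = 3L))
  expect_identical(make_label(cla, ft, 4), "GATC_1233")
  expect_identical(make_label(cla, ft, 2), "GA_12")
  expect_identical(make_label(cla, ft, 1), "G_1")
})

test_that("degenerate frequency tables get the fixed code lengths", {
  expect_equal(assign_code_lengths(c(A = 1L, C = 1L, G = 1L, T = 1L, N = 0L)),
               c(A = 2L, C = 2L, G = 2L, T = 2L))
  expect_equal(assign_code_lengths(c(A = 7L, C = 0L, G = 0L, T = 0L, N = 0L)),
               c(A = 1L))
  expect_identical(make_label(c(A = 1L), c(A = 7L, C = 0L), 5), "A_1")
  expect_error(assign_code_lengths(c(A = 0L, C = 0L)), "no positive counts")
})

test_that("code lengths attain the brute-force optimal prefix-code cost and Kraft equality", {
  set.seed(101)
  for (i in 1:400) {
    ft <- random_freq_table()
    cla <- assign_code_lengths(ft)
    present <- ft[ft > 0]
    expect_equal(sum(cla * present[names(cla)]), optimal_prefix_cost(ft))
    kraft <- sum(2^(-cla))
    if (length(cla) >= 2) expect_equal(kraft, 1) else expect_lte(kraft, 1)
  }
})

test_that("identical frequency tables give byte-identical labels, and truncation is prefix-consistent", {
  set.seed(202)
  for (i in 1:200) {
    ft <- random_freq_table()
    cla <- assign_code_lengths(ft)
    expect_identical(make_label(cla, ft, 5),
                     make_label(assign_code_lengths(ft), ft, 5))
    full <- make_label(cla, ft, 5)
    parts <- strsplit(full, "_", fixed = TRUE)[[1]]
    for (k in seq_len(nchar(parts[1]))) {
      lab_k <- make_label(cla, ft, k)
      pk <- strsplit(lab_k, "_", fixed = TRUE)[[1]]
      expect_identical(pk[1], substr(parts[1], 1, k))
      expect_identical(pk[2], substr(parts[2], 1, k))
    }
  }
})

test_that("label symbol count equals min(k, present symbols) and digits are non-decreasing", {
  set.seed(303)
  for (i in 1:100) {
    ft <- random_freq_table()
    k <- sample(1:5, 1)
    lab <- make_label(assign_code_lengths(ft), ft, k)
    parts <- strsplit(lab, "_", fixed = TRUE)[[1]]
    expect_equal(nchar(parts[1]), min(k, sum(ft > 0)))
    expect_equal(nchar(parts[2]), nchar(parts[1]))
    digits <- as.integer(strsplit(parts[2], "")[[1]])
    expect_true(all(diff(digits) >= 0))
  }
})
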