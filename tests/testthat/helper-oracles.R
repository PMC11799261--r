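# Shared fixtures and independent oracles, built in code.

# Independent oracle for optimal prefix-code cost: enumerate every length
# vector with per-symbol lengths in 1..4 (sufficient for <= 5 symbols: a
# binary code tree on m leaves has depth <= m - 1) satisfying the Kraft
# inequality, and take the minimum weighted total length. Independent of the
# Huffman construction under test.
prefix_code_length_sets <- local({
  cache <- list()
  function(m) {
    key <- as.character(m)
    if (is.null(cache[[key]])) {
      if (m == 1L) {
        cache[[key]] <<- matrix(1L, 1L, 1L)
      } else {
        grid <- as.matrix(expand.grid(rep(list(1:4), m)))
        kraft <- rowSums(2^(-grid))
        cache[[key]] <<- grid[kraft <= 1 + 1e-12, , drop = FALSE]
      }
    }
    cache[[key]]
  }
})

optimal_prefix_cost <- function(counts) {
  counts <- counts[counts > 0]
  sets <- prefix_code_length_sets(length(counts))
  min(as.vector(sets %*% counts))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T", "N"),
                       prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# a random frequency table over the DNA alphabet, >= 1 present symbol
random_freq_table <- function(max_count = 20L) {
  repeat {
    counts <- sample(0:max_count, 5L, replace = TRUE)
    if (any(counts > 0)) break
  }
  stats::setNames(counts, c("A", "C", "G", "T", "N"))
}

# random FASTA content exercising case, IUPAC letters, ragged widths,
# empty lines, and optional trailing newline
random_fasta_text <- function(n_records = NULL) {
  if (is.null(n_records)) n_records <- sample(1:4, 1L)
  chars <- c(strsplit("ACGTNacgtnRYSWKMrykm-", "")[[1]])
  recs <- vapply(seq_len(n_records), function(i) {
    n_lines <- sample(0:5, 1L)
    lines <- vapply(seq_len(n_lines), function(j)
      paste(sample(chars, sample(0:80, 1L), replace = TRUE), collapse = ""),
      character(1L))
    paste(c(sprintf(">rec%d desc %d", i, sample(1e6, 1L)), lines),
          collapse = "\n")
  }, character(1L))
  out <- paste(recs, collapse = "\n")
  if (sample(c(TRUE, FALSE), 1L)) out <- paste0(out, "\n")
  out
}
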