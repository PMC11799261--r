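Package: ostdna
Title: Lossless Reference-Free Genome Compression by Composition Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a classify-then-bin lossless codec for DNA sequences.
    Fixed-length windows of a genome are labelled by the code-length profile
    of a canonical Huffman tree built over their base composition; windows
    sharing a label are pooled into bins, each bin is compressed
    independently with a pluggable general-purpose backend (deflate, bzip2,
    xz), and the result is written as a single self-describing archive that
    decompresses bit-exactly to the input. Includes FASTA preprocessing in
    both a destructive one-line mode and a fully lossless mode with sidecar
    metadata, a synthetic-genome generator with regionally skewed base
    composition and distant repeat families, and a benchmarking harness that
    sweeps window and label lengths against the standalone backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
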