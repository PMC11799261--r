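---
title: "Composition binning for lossless genome compression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition binning for lossless genome compression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ostdna)
```

## The model

`ostdna` implements a classify-then-bin codec. The premise is two
empirical observations about genome sequence. First, *local* windows (on
the order of hundreds of bases) frequently have skewed base composition
even though the genome-wide distribution is close to uniform. Second,
regions that would compress well together — repeat copies, segments of
similar composition — are frequently separated by distances far beyond the
sliding windows of LZ-family codecs or the blocks of BWT-based ones, so a
general-purpose compressor never gets to exploit their mutual redundancy.

The codec therefore reorganizes the text before any general-purpose
compression happens. A one-line genome \(T\) of length \(t\) over
\(\Sigma = \{A,C,G,T,N\}\) is cut into \(\lceil t/w \rceil\)
non-overlapping windows. Each window is summarized by the code-length
profile of a canonical Huffman tree built on its symbol frequencies: the
label is the present symbols sorted by (code length ascending, frequency
descending, alphabet order), paired with those lengths — e.g. `GATC_1233`
— and truncated to its first \(k\) symbols. Windows sharing a (truncated)
label are concatenated, in order of appearance, into one *bin*; the
per-window label sequence \(L\) is kept. Each bin is compressed
independently by a backend codec, \(L\) is itself entropy-coded (the label
of a larger bin is necessarily more frequent in \(L\), so it gets a
shorter code), and everything is serialized into one archive.
Decompression decodes \(L\), decompresses the bins, and replays \(L\) with
one read-cursor per bin.

The label is deliberately crude: it measures only the *shape* of the
within-window frequency distribution, not sequence similarity. That is
what makes the pass cheap — one Huffman construction over at most five
symbols per window, so \(O(t)\) overall with a constant-size alphabet —
while still grouping windows whose composition bias the backend can
exploit jointly.

## Tunable parameters

* **Window length `w`** (bases, default 250). Windows much shorter than
  ~100 bases carry too little signal for a stable frequency estimate;
  windows beyond a few kilobases average composition out toward uniform.
  250–1000 is the productive range on genome-scale input; 250 pairs best
  with the bundled bzip2 backend at `k = 2`, which is why both are the
  defaults.
* **Label length `k`** (symbols, default 2). `k = 1` keeps only the
  dominant symbol and its code length (at most ~20 labels over this
  alphabet); `k = 5` keeps the full profile. More bins mean purer bins but
  also more per-bin compression start-up cost and a longer label
  dictionary, so intermediate values tend to win; `sweep_grid()` measures
  the trade-off on any given input.
* **Backend** (default `bzip2`). Registered backends are `identity`,
  `deflate`, `bzip2`, `xz`, all via base R's `memCompress` with library
  defaults, single-threaded. Ids 4 and 5 in the archive format are
  reserved for zstd and brotli plugins. The `identity` backend exists for
  exact overhead accounting: with it, archive size equals \(t\) plus the
  coded \(L\) plus fixed layout bytes.

## The archive format

All integers are little-endian; strings are length-prefixed. Layout:
magic `OST1`, version byte, `k` (u8), `w` (u32), backend id (u8),
alphabet (u8 length + bytes), `t` (u64), SHA-256 of \(T\) (32 bytes),
bin count (u32), label dictionary (u32 count; per label u16 length +
bytes + u8 code length), \(L\) entry count (u64), \(L\) payload (u32 byte
length + bit-packed canonical codes, MSB-first per code, packed LSB-first
into bytes, zero-padded to a byte boundary), then per bin in dictionary
order: label id (u32), blob length (u64), blob bytes; finally a sidecar
block (u32 length, 0 when absent). Identical inputs and parameters
produce byte-identical archives: bins are keyed by first appearance, the
Huffman constructions are deterministic, and no timestamps or randomness
enter the container.

## Numerical and degenerate-case choices

* **Single-symbol windows.** A one-leaf Huffman tree has a zero-bit code;
  the codec assigns length 1 (a real emitted code needs at least one
  bit), so homogeneous windows label as `A_1`, `N_1`, etc.
* **Tie-breaking.** Huffman merges take (lower weight, then earlier node
  creation, then alphabet order); label symbol order is (length
  ascending, frequency descending, alphabet order). Any fixed rule would
  do — what matters is that labels are deterministic across runs and
  platforms, so R's stable radix sort is used explicitly.
* **Absent symbols** never appear in a label: two windows with different
  present-symbol sets never share a full-length label.
* **The final partial window** (when \(w \nmid t\)) is labelled and
  binned like any other; its length is recovered from \(t\) in the
  header.
* **Label-stream coding.** Canonical codes are reconstructed at decode
  time from the stored per-label code lengths, so the decoder never
  re-runs Huffman on frequencies. With a single distinct label the
  payload is empty and only the entry count is stored. Code values are
  handled as doubles (exact below \(2^{53}\)); depths anywhere near that
  bound would require label-frequency sequences growing like Fibonacci
  numbers over astronomically long inputs.
* **Integrity.** The archive stores a SHA-256 of the one-line text;
  decompression recomputes and compares it after reassembly. Structural
  damage is usually caught earlier (backend corruption errors, bin-cursor
  overrun or leftover, truncation), but the checksum is the backstop that
  makes "lossless" checkable rather than asserted.

## FASTA handling: two deliberate modes

The benchmarking convention in this field compresses *one-line genomes*:
headers, newlines, lowercase (soft-masked) bases and non-ACGTN characters
are removed outright. `paper_preprocess()` reproduces exactly that
destructive rule — lowercase bases are deleted, not uppercased — because
comparability with published ratios requires it. `lossless_flatten()` is
the production alternative: it uppercases instead of deleting, records
lowercase runs as zero-based half-open intervals in final-text
coordinates, extracts non-ACGTN characters as (insertion position,
character) pairs, and keeps headers and per-line lengths, so
`restore_fasta()` is byte-exact. Dropped-character positions are indexed
in the final one-line coordinate system and re-inserted right-to-left,
which keeps earlier positions valid and preserves the original order of
ties. The sidecar travels inside the archive as one additional
backend-compressed JSON blob; paper mode stores nothing.

## What the synthetic generator emulates — and what it does not

`generate_genome()` produces the two features the codec targets:

* segments of length 500–2000 whose base probabilities are drawn from a
  Dirichlet with concentration \(\alpha = 0.3\) (strong regional skew);
* 20 repeat families, 3 copies each of 2000 bases, 1% per-base point
  mutation per copy, copies of a family at least \(10^5\) bases apart —
  similar sequence deliberately placed beyond small sliding windows;
* sparse `N` runs (rate 2×10⁻⁶ runs/base, lengths 100–1000), overlaid
  last the way assembly gaps cut through real annotation.

The default genome length is \(10^7\) bases: large enough that distant
redundancy genuinely falls outside a 900 KB bzip2 block, small enough
that a ten-seed comparison runs in minutes on one CPU — these are the
study conditions for every reported number here, chosen once and not
revisited per result. Generation is byte-reproducible given the seed
(Mersenne-Twister with fixed normal and sample kinds, stated explicitly
so fixtures survive R version changes).

What it does *not* model: genes and codon structure, GC isochores,
transposon families with realistic length/divergence spectra, tandem
repeats, or sequencing error. Passing tests on these genomes therefore
demonstrate that the pipeline is lossless, deterministic and beneficial
*when the two motivating properties hold*; they do not predict the size
of the benefit on any particular real genome, where composition skew and
repeat content differ widely.

## Design decisions that were genuinely open

* **Bin order and member order** are both first-appearance order. The
  inverse transform needs *some* fixed member order; appearance order
  makes the cursor replay trivially correct and archives deterministic.
* **Each bin is compressed as one blob.** Per-window compression would
  destroy the entire benefit (start-up costs dominate at window scale);
  per-bin compression is the point of the reorganization.
* **Ratios are reported on whole archives.** The honest cost of the
  method includes the header and the coded label stream. Because bins
  compressed as separate files (without container overhead) are the
  convention elsewhere, `sweep_grid()` also reports `binsonly_bytes`.
* **Strict monotonicity of label codes.** A strictly more frequent label
  never receives a longer code; equally frequent labels may differ in
  length (any Huffman code has this property — equal weights can sit at
  different depths), so that is the form the package asserts.
* **Problem sizes in the test suite.** The fuzz suites run 1000 round
  trips (texts up to 10⁴ bases across the full 6×5×4 parameter grid), the
  labeling oracle sweeps all 53,129 positive-count multisets (counts ≤ 20,
  ≤ 5 symbols) — the full space on which prefix-code cost depends — plus
  10⁴ random tables, and the benefit comparison uses ten 10 Mb genomes;
  together they complete in a few minutes on one CPU.

## Known limitations

* The label alphabet digit format supports code lengths up to one decimal
  digit, which is sufficient for alphabets up to ~10 symbols; larger
  alphabets would need delimited digits (documented, not implemented).
* Variable or adaptive window lengths, nested sub-binning, and non-DNA
  media are out of scope.
* zstd and brotli backends are interface-reserved but not bundled.
* On inputs smaller than the backend's own block/window size, binning
  overhead (header + label stream) can exceed the benefit; the codec is
  honest about this — `compare_vs_standalone()` will simply report a
  negative delta.
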