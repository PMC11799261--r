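# Synthetic genomes for testing the codec without downloads. The generator
# emulates the two properties of real assemblies the codec exploits:
# regionally skewed base composition (Dirichlet-distributed per-segment base
# probabilities) and similar subsequences that are far apart (planted repeat
# families with enforced minimum spacing, beyond typical LZ window ranges).

#' Configuration for the synthetic-genome generator
#'
#' @param total_length Genome length in bases.
#' @param segment_min,segment_max Segment lengths are drawn uniformly from
#'   this range; each segment gets its own base composition.
#' @param alpha Dirichlet concentration over A,C,G,T for per-segment base
#'   probabilities. Lower `alpha` means stronger skew; at the default 0.3
#'   most segments are dominated by one or two bases, mimicking
#'   composition-biased genomic regions.
#' @param n_run_rate Expected number of `N` runs per base (runs, not bases).
#'   The default 2e-6 plants on the order of 20 assembly-gap-like runs in a
#'   10 Mb genome.
#' @param n_run_min,n_run_max Length range of each `N` run.
#' @param n_families Number of repeat families.
#' @param repeat_length Length of each family's consensus, in bases.
#' @param copies_per_family Copies planted per family.
#' @param mutation_rate Per-base point-mutation probability applied
#'   independently to each planted copy.
#' @param min_spacing Minimum distance in bases between two copies of the
#'   same family — large by default (1e5) so the repeats sit beyond the
#'   reach of small sliding-window matchers.
#' @param seed Integer seed; generation is byte-reproducible given the
#'   config (Mersenne-Twister, fixed sampler settings).
#' @return An object of class `ost_gencfg`.
#' @export
generator_config <- function(total_length = 1e7,
                             segment_min = 500L, segment_max = 2000L,
                             alpha = 0.3,
                             n_run_rate = 2e-6,
                             n_run_min = 100L, n_run_max = 1000L,
                             n_families = 20L, repeat_length = 2000L,
                             copies_per_family = 3L,
                             mutation_rate = 0.01,
                             min_spacing = 1e5,
                             seed = 1L) {
  stopifnot(total_length >= 1, segment_min >= 1, segment_max >= segment_min,
            alpha > 0, n_run_rate >= 0, n_run_min >= 1,
            n_run_max >= n_run_min, n_families >= 0, repeat_length >= 1,
            copies_per_family >= 0, mutation_rate >= 0, mutation_rate <= 1,
            min_spacing >= 0)
  structure(list(total_length = as.numeric(total_length),
                 segment_min = as.integer(segment_min),
                 segment_max = as.integer(segment_max),
                 alpha = alpha, n_run_rate = n_run_rate,
                 n_run_min = as.integer(n_run_min),
                 n_run_max = as.integer(n_run_max),
                 n_families = as.integer(n_families),
                 repeat_length = as.integer(repeat_length),
                 copies_per_family = as.integer(copies_per_family),
                 mutation_rate = mutation_rate,
                 min_spacing = as.numeric(min_spacing),
                 seed = as.integer(seed)),
            class = "ost_gencfg")
}

# run expr under a private, fully specified RNG; restore caller state
.with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a synthetic genome
#'
#' Segments with independently drawn skewed base compositions are
#' concatenated to the target length; repeat-family copies (independently
#' point-mutated) are then planted at positions honouring the family's
#' minimum spacing and never overlapping one another; `N` runs are overlaid
#' last. Deterministic given the config (including its seed).
#'
#' @param cfg [generator_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A one-line genome string over `{A,C,G,T,N}`. The planted repeat
#'   coordinates are attached as attribute `"repeats"` — a data frame with
#'   `family`, `start`, `end` (1-based inclusive) — so tests can verify the
#'   copies are really there.
#' @export
generate_genome <- function(cfg = generator_config(), seed = NULL) {
  stopifnot(inherits(cfg, "ost_gencfg"))
  if (is.null(seed)) seed <- cfg$seed
  .with_rng(seed, {
    total <- cfg$total_length
    bases <- c("A", "C", "G", "T")
    # 1. composition-skewed segments
    n_guess <- ceiling(total / cfg$segment_min) + 1L
    lens <- cfg$segment_min +
      sample.int(cfg$segment_max - cfg$segment_min + 1L, n_guess,
                 replace = TRUE) - 1L
    cum <- cumsum(as.numeric(lens))
    n_seg <- which(cum >= total)[1L]
    lens <- lens[seq_len(n_seg)]
    segs <- lapply(lens, function(l) {
      p <- stats::rgamma(4L, shape = cfg$alpha)
      if (all(p == 0)) p <- rep(1, 4L)           # guards alpha -> 0 underflow
      paste(sample(bases, l, replace = TRUE, prob = p / sum(p)),
            collapse = "")
    })
    s <- substr(paste(unlist(segs), collapse = ""), 1L, total)
    # 2. distant repeat families
    rep_family <- integer(0)
    rep_start <- numeric(0)
    if (cfg$n_families > 0L && cfg$copies_per_family > 0L) {
      rl <- cfg$repeat_length
      if (rl > total) stop("infeasible placement: repeat longer than genome")
      occupied_start <- numeric(0)
      occupied_end <- numeric(0)
      for (fam in seq_len(cfg$n_families)) {
        consensus <- sample(bases, rl, replace = TRUE)
        starts <- numeric(0)
        for (cp in seq_len(cfg$copies_per_family)) {
          placed <- FALSE
          for (try in seq_len(2000L)) {
            st <- sample.int(total - rl + 1L, 1L)
            if (length(starts) && min(abs(starts - st)) < cfg$min_spacing)
              next
            if (length(occupied_start) &&
                any(st < occupied_end & st + rl > occupied_start))
              next
            starts <- c(starts, st)
            occupied_start <- c(occupied_start, st)
            occupied_end <- c(occupied_end, st + rl)
            placed <- TRUE
            break
          }
          if (!placed)
            stop(sprintf(
              "infeasible placement: family %d copy %d cannot honour spacing %g",
              fam, cp, cfg$min_spacing))
        }
        for (st in starts) {
          copy <- consensus
          n_mut <- stats::rbinom(1L, rl, cfg$mutation_rate)
          if (n_mut > 0L) {
            pos <- sample.int(rl, n_mut)
            copy[pos] <- vapply(copy[pos], function(b)
              sample(bases[bases != b], 1L), character(1L))
          }
          substr(s, st, st + rl - 1L) <- paste(copy, collapse = "")
        }
        rep_family <- c(rep_family, rep.int(fam, length(starts)))
        rep_start <- c(rep_start, starts)
      }
    }
    # 3. N runs, overlaid last (may hit segments or repeats, like real gaps)
    n_runs <- stats::rpois(1L, cfg$n_run_rate * total)
    if (n_runs > 0L) {
      for (i in seq_len(n_runs)) {
        l <- cfg$n_run_min +
          sample.int(cfg$n_run_max - cfg$n_run_min + 1L, 1L) - 1L
        l <- min(l, total)
        st <- sample.int(total - l + 1L, 1L)
        substr(s, st, st + l - 1L) <- strrep("N", l)
      }
    }
    attr(s, "repeats") <- data.frame(family = rep_family, start = rep_start,
                                     end = rep_start + cfg$repeat_length - 1)
    s
  })
}

#' Per-window base composition summary
#'
#' Exact per-window symbol counts and frequencies; the diagnostic used to
#' verify that generated genomes actually carry regional composition skew.
#'
#' @param text One-line genome.
#' @param w Window length.
#' @param alphabet Ordered alphabet.
#' @return A data frame with one row per window: `window`, `start` (1-based),
#'   `length`, one count column per symbol, and one `freq_<symbol>` column.
#' @export
describe_composition <- function(text, w, alphabet = DNA_ALPHABET) {
  counts <- .window_count_matrix(text, as.integer(w), alphabet)
  lens <- rowSums(counts)
  out <- data.frame(window = seq_len(nrow(counts)),
                    start = (seq_len(nrow(counts)) - 1L) * as.integer(w) + 1L,
                    length = as.integer(lens))
  for (j in seq_along(alphabet)) out[[alphabet[j]]] <- counts[, j]
  for (j in seq_along(alphabet))
    out[[paste0("freq_", alphabet[j])]] <- counts[, j] / lens
  out
}

#' Write a genome as FASTA or raw one-line text
#'
#' @param text Genome string.
#' @param path Output path.
#' @param format `"fasta"` (wrapped at `width` columns) or `"raw"` (the bare
#'   sequence, no trailing newline).
#' @param header FASTA header (without `>`).
#' @param width Line width for FASTA output.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(text, path, format = c("fasta", "raw"),
                         header = "synthetic", width = 70L) {
  format <- match.arg(format)
  if (format == "raw") {
    writeBin(charToRaw(text), path)
  } else {
    t <- nchar(text)
    starts <- seq.int(1L, t, by = width)
    lines <- substring(text, starts, pmin(starts + width - 1L, t))
    writeBin(charToRaw(paste0(">", header, "\n",
                              paste(lines, collapse = "\n"), "\n")), path)
  }
  invisible(path)
}
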