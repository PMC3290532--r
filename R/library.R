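#' Sample a short-insert clone library from a genome
#'
#' Emulates random shotgun cloning: clone start positions are uniform over
#' the genome, insert lengths are drawn from a normal distribution truncated
#' below at `min_insert` (a distributional choice; real libraries are
#' size-selected around a mean), and every clone is a verbatim substring of
#' the genome — divergence is a property of the genome copies, not of the
#' Sanger-grade clone sequences. The genome-coverage fraction
#' f = total insert bp / genome size is recorded: its reciprocal later
#' scales hit counts to copies per genome.
#'
#' @param genome a `synthetic_genome` or a single character sequence.
#' @param n_clones number of clones to sample.
#' @param insert_mean,insert_sd mean and sd of insert length in bp.
#' @param min_insert lower truncation bound for insert length.
#' @param seed integer seed.
#' @return a `clone_library`: tibble with columns `id`, `sequence`,
#'   `length`, and ground-truth `start`/`end` (0-based half-open source
#'   coordinates), carrying attributes `n_clones`, `mean_insert_bp`,
#'   `total_insert_bp`, `source_genome_size_bp` and `coverage_fraction`.
#'   `glance()` returns these as a one-row tibble.
#' @export
#' @examples
#' g <- build_genome(genome_spec(50000, seed = 7))
#' lib <- sample_clone_library(g, 20, insert_mean = 603, seed = 7)
#' glance(lib)
sample_clone_library <- function(genome, n_clones, insert_mean = 603,
                                 insert_sd = 150, min_insert = 50, seed = 1) {
  seqs <- as_sequences(genome, "genome")
  if (length(seqs) != 1) abort("`genome` must be a single sequence")
  g <- unname(seqs)
  G <- nchar(g)
  if (n_clones < 0) abort("`n_clones` must be non-negative")
  if (insert_mean < 1) abort("`insert_mean` must be at least 1")
  if (insert_mean > G) {
    abort(sprintf("`insert_mean` (%s bp) exceeds the genome length (%s bp)",
                  format(insert_mean, big.mark = ","), format(G, big.mark = ",")))
  }
  n_clones <- as.integer(n_clones)
  with_stage_seed(seed, "sample_clone_library", {
    lens <- pmin(pmax(round(stats::rnorm(n_clones, insert_mean, insert_sd)),
                      min_insert), G)
    starts <- vapply(lens, function(l) sample.int(G - l + 1L, 1), integer(1))
  })
  clones <- if (n_clones == 0) {
    tibble(id = character(), sequence = character(), length = integer(),
           start = integer(), end = integer())
  } else {
    tibble(
      id = sprintf("clone_%05d", seq_len(n_clones)),
      sequence = substring(g, starts, starts + lens - 1),
      length = as.integer(lens),
      start = as.integer(starts - 1L),
      end = as.integer(starts + lens - 1L)
    )
  }
  total <- sum(clones$length)
  structure(
    clones,
    class = c("clone_library", class(clones)),
    n_clones = n_clones,
    mean_insert_bp = if (n_clones > 0) total / n_clones else 0,
    total_insert_bp = as.integer(total),
    source_genome_size_bp = G,
    coverage_fraction = total / G,
    seed = seed
  )
}

#' @rdname sample_clone_library
#' @param x a `clone_library`.
#' @param ... unused.
#' @method glance clone_library
#' @export
glance.clone_library <- function(x, ...) {
  tibble(
    n_clones = attr(x, "n_clones"),
    mean_insert_bp = attr(x, "mean_insert_bp"),
    total_insert_bp = attr(x, "total_insert_bp"),
    source_genome_size_bp = attr(x, "source_genome_size_bp"),
    coverage_fraction = attr(x, "coverage_fraction")
  )
}

#' Simulate a shotgun read set from a genome
#'
#' Draws uniform-start reads with normally distributed lengths (truncated
#' below at 30 bp) and i.i.d. per-base substitution errors. Stands in for
#' the pyrosequencing read databases used for copy-number profiling.
#'
#' @param genome a `synthetic_genome` or a single character sequence.
#' @param n_reads number of reads.
#' @param read_len_mean,read_len_sd read length distribution in bp.
#' @param error_rate per-base substitution error rate in \[0, 0.2\].
#' @param seed integer seed.
#' @return a `read_set`: tibble with columns `id`, `sequence`, `length`,
#'   plus attribute `total_read_bp`; `glance()` summarises it.
#' @export
simulate_reads <- function(genome, n_reads, read_len_mean = 400,
                           read_len_sd = 40, error_rate = 0, seed = 1) {
  seqs <- as_sequences(genome, "genome")
  if (length(seqs) != 1) abort("`genome` must be a single sequence")
  g <- unname(seqs)
  G <- nchar(g)
  if (n_reads < 0) abort("`n_reads` must be non-negative")
  if (error_rate < 0 || error_rate > 0.2) abort("`error_rate` must lie in [0, 0.2]")
  n_reads <- as.integer(n_reads)
  with_stage_seed(seed, "simulate_reads", {
    lens <- pmin(pmax(round(stats::rnorm(n_reads, read_len_mean, read_len_sd)),
                      30), G)
    starts <- vapply(lens, function(l) sample.int(G - l + 1L, 1), integer(1))
    reads <- if (n_reads == 0) character(0) else {
      substring(g, starts, starts + lens - 1)
    }
    if (error_rate > 0 && n_reads > 0) {
      reads <- vapply(reads, mutate_sequence, character(1), rate = error_rate,
                      USE.NAMES = FALSE)
    }
  })
  out <- tibble(
    id = sprintf("read_%06d", seq_len(n_reads)),
    sequence = reads,
    length = as.integer(lens)
  )
  structure(
    out,
    class = c("read_set", class(out)),
    total_read_bp = sum(out$length),
    seed = seed
  )
}

#' @rdname simulate_reads
#' @param x a `read_set`.
#' @param ... unused.
#' @method glance read_set
#' @export
glance.read_set <- function(x, ...) {
  tibble(n_reads = nrow(x), total_read_bp = attr(x, "total_read_bp"),
         mean_read_bp = if (nrow(x) > 0) mean(x$length) else 0)
}
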