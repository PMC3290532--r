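# Core estimator: clone-hit counts -> copies per genome -> genome fractions.
# The library samples a fraction f of the genome; screening counts one clone
# as one hit; dividing hits by f scales the library count to the whole
# genome, and multiplying by the family's mean element size converts copy
# number to the genome fraction occupied.

#' Genome-coverage fraction of a clone library
#'
#' f = total insert bp / genome size. When the exact per-clone lengths are
#' known (a `clone_library`, or `total_insert_bp` supplied) the exact sum is
#' preferred over `n_clones * mean_insert_bp`.
#'
#' @param n_clones number of clones, or a `clone_library` object.
#' @param mean_insert_bp mean insert size in bp.
#' @param genome_size_bp haploid genome size in bp.
#' @param total_insert_bp optional exact summed insert length in bp.
#' @return the coverage fraction f (plain numeric).
#' @export
#' @examples
#' coverage_fraction(7720, 603, 1102500000)  # ~0.42% of the genome
coverage_fraction <- function(n_clones, mean_insert_bp = NULL,
                              genome_size_bp = NULL, total_insert_bp = NULL) {
  if (inherits(n_clones, "clone_library")) {
    lib <- n_clones
    return(attr(lib, "total_insert_bp") /
             (genome_size_bp %||% attr(lib, "source_genome_size_bp")))
  }
  if (is.null(genome_size_bp) || genome_size_bp <= 0) {
    abort("`genome_size_bp` must be positive")
  }
  if (n_clones < 0) abort("`n_clones` must be non-negative")
  if (!is.null(total_insert_bp)) return(total_insert_bp / genome_size_bp)
  n_clones * mean_insert_bp / genome_size_bp
}

#' Scale a hit count to copies per genome
#'
#' The library covers fraction f of the genome, so a family observed in
#' `hits` clones is present in about hits / f copies genome-wide. The
#' quotient is floored to an integer copy count (the flooring convention is
#' the one that exactly regenerates published survey tables; see the
#' vignette).
#'
#' @param hits integer clone-hit count (one clone = one hit).
#' @param f library coverage fraction from [coverage_fraction()].
#' @return integer copies per genome.
#' @export
#' @examples
#' copies_per_genome(118, 0.0042)  # 28095
copies_per_genome <- function(hits, f) {
  if (any(hits < 0)) abort("`hits` must be non-negative")
  if (any(f <= 0) && any(hits > 0)) {
    abort("coverage fraction f = 0: the library covers none of the genome")
  }
  ifelse(hits == 0, 0L, as.integer(floor(hits / f + 1e-9)))
}

#' Genome fraction occupied by a family
#'
#' p = copies x mean element size / genome size, clamped to 1 with a warning
#' if the product exceeds the genome.
#'
#' @param copies copies per genome.
#' @param mean_element_bp mean element size in bp.
#' @param genome_size_bp haploid genome size in bp.
#' @return fraction of the genome occupied (0..1).
#' @export
#' @examples
#' genome_fraction(11190, 11035, 1102500000)  # ~0.112
genome_fraction <- function(copies, mean_element_bp, genome_size_bp) {
  if (any(copies < 0) || any(mean_element_bp < 0)) {
    abort("`copies` and `mean_element_bp` must be non-negative")
  }
  if (any(genome_size_bp <= 0)) abort("`genome_size_bp` must be positive")
  p <- copies * mean_element_bp / genome_size_bp
  if (any(p > 1)) {
    warn("genome fraction exceeds 1; clamping (element size or copy number inconsistent with genome size)")
    p <- pmin(p, 1)
  }
  p
}

#' Exact binomial confidence interval on copies per genome
#'
#' Clopper-Pearson interval on the per-clone hit probability, transformed
#' through the copies-per-genome map (x N / f). Bounds are floored /
#' ceiled so the point estimate always lies inside.
#'
#' @param hits clone-hit count.
#' @param n_clones library size.
#' @param f library coverage fraction.
#' @param confidence confidence level in (0.5, 1).
#' @return one-row tibble: `ci_low`, `ci_high` (copies per genome scale).
#' @export
hit_count_ci <- function(hits, n_clones, f, confidence = 0.95) {
  if (hits < 0 || hits > n_clones) abort("`hits` must lie in [0, n_clones]")
  if (confidence <= 0.5 || confidence >= 1) {
    abort("`confidence` must lie in (0.5, 1)")
  }
  alpha <- 1 - confidence
  p_lo <- if (hits == 0) 0 else stats::qbeta(alpha / 2, hits, n_clones - hits + 1)
  p_hi <- if (hits == n_clones) 1 else {
    stats::qbeta(1 - alpha / 2, hits + 1, n_clones - hits)
  }
  scale <- n_clones / f
  tibble(ci_low = floor(p_lo * scale), ci_high = ceiling(p_hi * scale))
}

#' Ratio of two genome-fraction percentages
#'
#' The cross-species expansion ratio: fraction in species A over fraction in
#' species B, rounded half-up. A family absent from both species yields 0
#' (the tabulation convention for all-zero rows); a family present in A but
#' absent from B is signalled as infinite expansion.
#'
#' @param p_a,p_b genome-fraction percentages (same units, vectorised).
#' @param decimals decimal places for half-up rounding.
#' @return numeric ratio vector; `Inf` marks infinite expansion.
#' @export
#' @examples
#' compare_fractions(10.1, 3.6)   # 2.81
#' compare_fractions(0.1, 0.02, 0)  # 5
compare_fractions <- function(p_a, p_b, decimals = 2) {
  if (any(p_a < 0) || any(p_b < 0)) abort("fractions must be non-negative")
  out <- numeric(length(p_a))
  zero_both <- p_a == 0
  inf <- p_a > 0 & p_b == 0
  ok <- !zero_both & !inf
  out[zero_both] <- 0
  if (any(inf)) {
    warn("fraction present in A but zero in B: infinite expansion")
    out[inf] <- Inf
  }
  out[ok] <- round_half_up(p_a[ok] / p_b[ok], decimals)
  out
}

#' Per-family abundance estimates from hit counts
#'
#' Runs the full estimator for every family: copies per genome
#' (hits / f, floored), genome fraction (copies x mean element size /
#' genome size) and a Clopper-Pearson confidence interval on copies.
#'
#' @param hits tibble with columns `family` and `hits`, or a
#'   `screen_result`.
#' @param element_sizes tibble with columns `family` and `mean_element_bp`.
#' @param n_clones library size.
#' @param genome_size_bp haploid genome size in bp.
#' @param f coverage fraction; computed from `n_clones` and
#'   `mean_insert_bp` when omitted.
#' @param mean_insert_bp mean insert size (used only when `f` is omitted).
#' @param confidence confidence level for the interval.
#' @return tibble with one row per family: `family`, `hits`,
#'   `coverage_fraction`, `copies_per_genome`, `mean_element_bp`,
#'   `genome_fraction`, `percent_of_genome`, `ci_low`, `ci_high`.
#' @export
estimate_abundance <- function(hits, element_sizes, n_clones, genome_size_bp,
                               f = NULL, mean_insert_bp = 603,
                               confidence = 0.95) {
  if (inherits(hits, "screen_result")) hits <- hit_counts(hits)
  hits <- as_tibble(hits)
  stopifnot(all(c("family", "hits") %in% names(hits)))
  if (is.null(f)) f <- coverage_fraction(n_clones, mean_insert_bp, genome_size_bp)
  out <- dplyr::left_join(hits, as_tibble(element_sizes), by = "family")
  if (anyNA(out$mean_element_bp)) {
    abort(sprintf("no mean element size for famil%s: %s",
                  if (sum(is.na(out$mean_element_bp)) == 1) "y" else "ies",
                  paste(out$family[is.na(out$mean_element_bp)], collapse = ", ")))
  }
  ci <- dplyr::bind_rows(lapply(out$hits, hit_count_ci, n_clones = n_clones,
                                f = f, confidence = confidence))
  out |>
    dplyr::mutate(
      coverage_fraction = f,
      copies_per_genome = copies_per_genome(.data$hits, f),
      genome_fraction = genome_fraction(.data$copies_per_genome,
                                        .data$mean_element_bp, genome_size_bp),
      percent_of_genome = 100 * .data$genome_fraction,
      ci_low = ci$ci_low,
      ci_high = ci$ci_high
    )
}
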