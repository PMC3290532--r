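# Perfect microsatellite detection: maximal runs of a primitive repeat
# unit, reported once per interval at the smallest primitive unit length.

# Lexicographically minimal rotation of a repeat unit; optionally also over
# the reverse complement's rotations (strand-merged accounting).
canonical_motif <- function(unit, merge_revcomp = FALSE) {
  vapply(unit, function(u) {
    n <- nchar(u)
    d <- paste0(u, u)
    rots <- substring(d, seq_len(n), seq_len(n) + n - 1)
    if (merge_revcomp) {
      rc <- revcomp(u)
      drc <- paste0(rc, rc)
      rots <- c(rots, substring(drc, seq_len(n), seq_len(n) + n - 1))
    }
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

# A unit is primitive when it is not a whole-number repetition of a shorter
# string, i.e. its minimal period equals its length.
is_primitive <- function(unit) {
  vapply(unit, function(u) {
    n <- nchar(u)
    if (n == 1) return(TRUE)
    divs <- which(n %% seq_len(n - 1) == 0)
    !any(vapply(divs, function(d) {
      strrep(substr(u, 1, d), n / d) == u
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

scan_one_sequence <- function(seq_id, x, unit_min, unit_max, min_units,
                              merge_revcomp) {
  check_alphabet(x)
  n <- nchar(x)
  runs <- list()
  if (n >= unit_min * min_units) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    valid <- chars %in% c("A", "C", "G", "T")  # N and ambiguity codes break runs
    for (u in unit_min:min(unit_max, floor(n / min_units))) {
      eq <- chars[seq_len(n - u)] == chars[(u + 1):n] &
        valid[seq_len(n - u)] & valid[(u + 1):n]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      hit <- which(r$values & r$lengths >= (min_units - 1) * u)
      for (h in hit) {
        s <- starts[h]                  # 1-based first base of the run
        region_len <- r$lengths[h] + u
        n_units <- region_len %/% u
        if (n_units < min_units) next
        unit <- substr(x, s, s + u - 1)
        if (!is_primitive(unit)) next   # reported at its smaller period instead
        runs[[length(runs) + 1L]] <- tibble(
          seq_id = seq_id,
          start = s - 1L,
          end = s + region_len - 1L,
          unit = unit,
          canonical_motif = canonical_motif(unit, merge_revcomp),
          unit_len = u,
          n_units = as.integer(n_units),
          length_bp = as.integer(region_len)
        )
      }
    }
  }
  if (length(runs) == 0) {
    tibble(seq_id = character(), start = integer(), end = integer(),
           unit = character(), canonical_motif = character(),
           unit_len = integer(), n_units = integer(), length_bp = integer())
  } else {
    dplyr::arrange(dplyr::bind_rows(runs), .data$start, .data$unit_len)
  }
}

#' Detect perfect microsatellite runs
#'
#' Finds every maximal perfect tandem run whose repeat unit is primitive
#' (not itself a repetition of a shorter string) and whose complete-unit
#' count reaches `min_units`. A trailing partial unit extends the run's
#' `length_bp` but does not count towards `n_units` (array sizes are
#' conventionally reported in bp). Each interval is reported once, at its
#' smallest primitive unit length, so dinucleotide arrays are not
#' double-counted inside the tetranucleotide class. Runs are broken at `N`
#' or any ambiguity base; lowercase (soft-masked) input is treated as
#' ordinary sequence.
#'
#' @param x sequences: named character vector, tibble with `id`/`sequence`
#'   columns (e.g. from [read_fasta()]), or `DNAStringSet`.
#' @param unit_min,unit_max unit-length range to scan (defaults 2-4; the
#'   classical tool accepts up to 100).
#' @param min_units minimum number of complete units (default 3).
#' @param merge_revcomp when `TRUE`, canonical motifs are additionally
#'   minimised over reverse-complement rotations so complementary-strand
#'   runs pool; off by default, matching per-strand motif reporting.
#' @return tibble of runs with 0-based half-open coordinates: `seq_id`,
#'   `start`, `end`, `unit` (as it occurs), `canonical_motif`, `unit_len`,
#'   `n_units`, `length_bp`.
#' @export
#' @examples
#' scan_microsatellites(c(locus = "GGACACACACGG"))
scan_microsatellites <- function(x, unit_min = 2, unit_max = 4, min_units = 3,
                                 merge_revcomp = FALSE) {
  if (unit_min < 1 || unit_min > unit_max) {
    abort("need 1 <= unit_min <= unit_max")
  }
  if (min_units < 2) abort("`min_units` must be at least 2")
  seqs <- as_sequences(x)
  dplyr::bind_rows(purrr::imap(seqs, function(s, id) {
    scan_one_sequence(id, s, as.integer(unit_min), as.integer(unit_max),
                      as.integer(min_units), merge_revcomp)
  }))
}

#' Summarise microsatellite runs per motif and per unit-length class
#'
#' @param runs tibble from [scan_microsatellites()].
#' @param seq_len total scanned sequence length in bp (denominator for
#'   percentages).
#' @param focus_motifs optional canonical motifs to pull into a dedicated
#'   subset table (e.g. motifs known to accumulate on a sex chromosome).
#' @return a `microsat_summary`: list of tibbles `by_motif`, `by_class`
#'   and (when requested) `focus`, each with run count, total bp,
#'   complete-unit bp, percentages of the scanned sequence, and the longest
#'   run. `tidy()` returns `by_motif`.
#' @export
summarize_runs <- function(runs, seq_len, focus_motifs = NULL) {
  if (seq_len <= 0) abort("`seq_len` must be positive")
  runs <- as_tibble(runs)
  if (nrow(runs) > 0 && any(runs$end > seq_len)) {
    abort("run coordinates exceed `seq_len`")
  }
  summarise_group <- function(df, key) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(
        n_runs = dplyr::n(),
        total_bp = sum(.data$length_bp),
        complete_unit_bp = sum(.data$n_units * .data$unit_len),
        percent_bp = 100 * sum(.data$length_bp) / seq_len,
        percent_complete_units = 100 * sum(.data$n_units * .data$unit_len) / seq_len,
        longest_bp = max(.data$length_bp),
        .groups = "drop"
      )
  }
  empty <- tibble(n_runs = integer(), total_bp = integer(),
                  complete_unit_bp = integer(), percent_bp = numeric(),
                  percent_complete_units = numeric(), longest_bp = integer())
  by_motif <- if (nrow(runs) > 0) {
    summarise_group(runs, c("canonical_motif", "unit_len"))
  } else {
    dplyr::bind_cols(tibble(canonical_motif = character(),
                            unit_len = integer()), empty)
  }
  by_class <- if (nrow(runs) > 0) {
    summarise_group(runs, "unit_len")
  } else {
    dplyr::bind_cols(tibble(unit_len = integer()), empty)
  }
  out <- list(by_motif = by_motif, by_class = by_class, seq_len = seq_len)
  if (!is.null(focus_motifs)) {
    out$focus <- by_motif[by_motif$canonical_motif %in%
                            canonical_motif(focus_motifs), ]
  }
  structure(out, class = "microsat_summary")
}

#' @rdname summarize_runs
#' @param x a `microsat_summary`.
#' @param ... unused.
#' @method tidy microsat_summary
#' @export
tidy.microsat_summary <- function(x, ...) x$by_motif

#' @export
print.microsat_summary <- function(x, ...) {
  cat(sprintf("<microsat_summary> over %s bp\n", format(x$seq_len, big.mark = ",")))
  print(x$by_class)
  invisible(x)
}
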