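# Per-position genomic copy-number profiles along a reference element from
# read similarity hits: local-alignment hits under a Karlin-Altschul
# E-value cutoff, per-base depth normalised by the read set's genome-wide
# expected depth.

#' Karlin-Altschul parameters for a nucleotide scoring scheme
#'
#' For ungapped scoring, lambda is the positive root of
#' sum p_i p_j exp(lambda * s_ij) = 1 under uniform base frequencies (for
#' +1/-1 this gives ln 3). K is not solved here; the fixed fallback pair
#' (lambda = 1.37, K = 0.711) is returned for gapped mode, where no simple
#' closed procedure exists.
#'
#' @param match,mismatch match and mismatch scores.
#' @param gapped use the fixed fallback pair instead of solving.
#' @param K_fallback K constant used alongside the solved lambda.
#' @return list with `lambda` and `K`.
#' @export
karlin_altschul_params <- function(match = 1, mismatch = -1, gapped = FALSE,
                                   K_fallback = 0.711) {
  if (gapped) return(list(lambda = 1.37, K = 0.711))
  if (match <= 0 || mismatch >= 0) {
    abort("need `match` > 0 and `mismatch` < 0 for Karlin-Altschul statistics")
  }
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  list(lambda = lambda, K = K_fallback)
}

# E = K * m * n * exp(-lambda * S), database length m = total read bp,
# query length n = element length.
evalue_from_score <- function(score, m, n, ka) {
  ka$K * as.numeric(m) * as.numeric(n) * exp(-ka$lambda * score)
}

#' Map reads onto a reference element by significant local alignment
#'
#' Aligns every read locally against the element (both strands), keeps one
#' best hit per read, and retains it when its Karlin-Altschul E-value —
#' computed with the total read bp as database size and the element length
#' as query size — is at most `e_cutoff`. Hit intervals are element
#' coordinates, 0-based half-open.
#'
#' @param element reference element sequence (character scalar, >= 100 bp).
#' @param reads a `read_set` or tibble with `id` and `sequence` columns.
#' @param match,mismatch,gap_open,gap_extend alignment scheme.
#' @param e_cutoff E-value threshold (default 1e-15).
#' @param seed_length exact k-mer seed prefilter; 0 disables.
#' @param gapped_stats use the fixed gapped-mode Karlin-Altschul constants.
#' @return tibble of hits: `read_id`, `start`, `end`, `strand`, `score`,
#'   `evalue`, with attributes `element_len` and `total_read_bp`.
#' @export
map_read_hits <- function(element, reads, match = 1, mismatch = -1,
                          gap_open = 2, gap_extend = 1, e_cutoff = 1e-15,
                          seed_length = 14, gapped_stats = FALSE) {
  el <- unname(as_sequences(element, "element"))
  if (length(el) != 1) abort("`element` must be a single sequence")
  if (!nzchar(el)) abort("`element` must be non-empty")
  if (nchar(el) < 100) abort("`element` must be at least 100 bp")
  if (e_cutoff <= 0) abort("`e_cutoff` must be positive")
  reads_tbl <- as_tibble(reads)
  total_read_bp <- attr(reads, "total_read_bp") %||%
    sum(nchar(reads_tbl$sequence))
  empty <- tibble(read_id = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(), evalue = numeric())
  if (nrow(reads_tbl) == 0) {
    return(structure(empty, element_len = nchar(el),
                     total_read_bp = total_read_bp))
  }
  stopifnot(all(c("id", "sequence") %in% names(reads_tbl)))
  ka <- karlin_altschul_params(match, mismatch, gapped = gapped_stats)
  cand <- kmer_candidates(reads_tbl$sequence, el, seed_length,
                          by_strand = TRUE)
  mat <- substitution_matrix(match, mismatch)
  subj <- Biostrings::DNAString(el)
  per_strand <- list()
  for (strand in c("+", "-")) {
    idx <- if (strand == "+") cand$fwd else cand$rev
    if (length(idx) == 0) next
    seqs <- reads_tbl$sequence[idx]
    pats <- Biostrings::DNAStringSet(if (strand == "+") seqs else revcomp(seqs))
    al <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    per_strand[[strand]] <- tibble(
      read_id = reads_tbl$id[idx],
      start = BiocGenerics::start(Biostrings::subject(al)) - 1L,
      end = BiocGenerics::end(Biostrings::subject(al)),
      strand = strand,
      score = pmax(0, Biostrings::score(al))
    )
  }
  if (length(per_strand) == 0) {
    return(structure(empty, element_len = nchar(el),
                     total_read_bp = total_read_bp))
  }
  # one best hit per read (strand ties resolve to the forward strand)
  best <- dplyr::bind_rows(per_strand) |>
    dplyr::arrange(.data$read_id, dplyr::desc(.data$score), .data$strand) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  best$evalue <- evalue_from_score(best$score, total_read_bp, nchar(el), ka)
  out <- best[best$evalue <= e_cutoff, ]
  structure(dplyr::arrange(out, .data$start),
            element_len = nchar(el), total_read_bp = total_read_bp)
}

#' Convert hit intervals to a genomic copy-number profile
#'
#' Per-base depth d(x) is the number of hit intervals covering position x;
#' the genomic copy number at x is d(x) divided by the read set's expected
#' per-base genome depth, total_read_bp / genome_size_bp. Windows report
#' the mean over their bases.
#'
#' @param hits tibble from [map_read_hits()] (columns `start`, `end`).
#' @param total_read_bp total bp of the read database (defaults to the
#'   attribute carried by `hits`).
#' @param genome_size_bp size of the genome the reads sample.
#' @param window_bp window width in bp (>= 1).
#' @param element_len element length (defaults to the attribute carried by
#'   `hits`).
#' @param dataset_id label stored with the profile (e.g. "male", "female").
#' @return a `coverage_profile` tibble: `window_start`, `window_end`
#'   (0-based half-open), `n_hits` (intervals overlapping the window),
#'   `depth` (mean per-base), `copies` (mean per-base genomic copy number),
#'   `dataset_id`; attributes keep the per-base depth and the dataset
#'   constants. `glance()` summarises.
#' @export
depth_to_copies <- function(hits, genome_size_bp, window_bp = 100,
                            total_read_bp = NULL, element_len = NULL,
                            dataset_id = "reads") {
  if (window_bp < 1) abort("`window_bp` must be at least 1")
  if (genome_size_bp <= 0) abort("`genome_size_bp` must be positive")
  total_read_bp <- total_read_bp %||% attr(hits, "total_read_bp")
  element_len <- element_len %||% attr(hits, "element_len")
  if (is.null(total_read_bp) || total_read_bp <= 0) {
    abort("`total_read_bp` must be positive")
  }
  if (is.null(element_len)) abort("`element_len` is required")
  hits <- as_tibble(hits)
  ir <- IRanges::IRanges(start = hits$start + 1L, end = hits$end)
  depth <- as.numeric(IRanges::coverage(ir, width = element_len))
  expected_depth <- total_read_bp / genome_size_bp
  n_win <- ceiling(element_len / window_bp)
  win_start <- (seq_len(n_win) - 1L) * as.integer(window_bp)
  win_end <- pmin(win_start + as.integer(window_bp), element_len)
  win_of_base <- rep(seq_len(n_win), times = win_end - win_start)
  depth_win <- as.numeric(tapply(depth, win_of_base, mean))
  wins <- IRanges::IRanges(start = win_start + 1L, end = win_end)
  n_hits <- IRanges::countOverlaps(wins, ir)
  out <- tibble(
    window_start = win_start,
    window_end = win_end,
    n_hits = as.integer(n_hits),
    depth = depth_win,
    copies = depth_win / expected_depth,
    dataset_id = dataset_id
  )
  structure(out, class = c("coverage_profile", class(out)),
            depth_per_base = depth,
            element_len = element_len,
            total_read_bp = total_read_bp,
            genome_size_bp = genome_size_bp,
            n_hits_total = nrow(hits))
}

#' Profile a reference element against a read set
#'
#' Convenience wrapper: [map_read_hits()] then [depth_to_copies()].
#'
#' @inheritParams map_read_hits
#' @inheritParams depth_to_copies
#' @param ... passed to [map_read_hits()].
#' @return a `coverage_profile` (see [depth_to_copies()]).
#' @export
coverage_profile <- function(element, reads, genome_size_bp, window_bp = 100,
                             dataset_id = "reads", ...) {
  hits <- map_read_hits(element, reads, ...)
  depth_to_copies(hits, genome_size_bp = genome_size_bp,
                  window_bp = window_bp, dataset_id = dataset_id)
}

#' @rdname depth_to_copies
#' @param x a `coverage_profile`.
#' @param ... unused.
#' @method glance coverage_profile
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble(
    element_len = attr(x, "element_len"),
    n_windows = nrow(x),
    n_hits = attr(x, "n_hits_total"),
    mean_copies = mean(x$copies),
    max_copies = max(x$copies),
    total_read_bp = attr(x, "total_read_bp"),
    genome_size_bp = attr(x, "genome_size_bp")
  )
}

#' Compare two element profiles on a shared alignment coordinate
#'
#' Globally aligns the two element sequences, computes a per-window
#' identity track over alignment columns, and projects both per-base
#' copy-number tracks onto the alignment (gap columns carry `NA` for the
#' gapped side). This is the central similarity panel of a two-element
#' profile figure: conserved regions show high identity, divergent LTRs and
#' accessory ORFs low.
#'
#' @param profile_a,profile_b `coverage_profile`s of the two elements.
#' @param element_a,element_b the element sequences the profiles describe.
#' @param window_bp identity window in alignment columns.
#' @param match,mismatch,gap_open,gap_extend global alignment scheme.
#' @return a `profile_comparison` tibble, one row per alignment column:
#'   `column` (1-based), `pos_a`, `pos_b` (0-based element positions, `NA`
#'   at gaps), `identity_window`, `copies_a`, `copies_b`.
#' @export
compare_profiles <- function(profile_a, profile_b, element_a, element_b,
                             window_bp = 100, match = 1, mismatch = -1,
                             gap_open = 2, gap_extend = 1) {
  ea <- unname(as_sequences(element_a, "element_a"))
  eb <- unname(as_sequences(element_b, "element_b"))
  if (!nzchar(ea) || !nzchar(eb)) abort("elements must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ea), Biostrings::DNAString(eb), type = "global",
    substitutionMatrix = substitution_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  a_chars <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b_chars <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  n_col <- length(a_chars)
  pos_a <- cumsum(a_chars != "-")        # 1-based element positions, 0 before first
  pos_b <- cumsum(b_chars != "-")
  pos_a[a_chars == "-"] <- NA
  pos_b[b_chars == "-"] <- NA
  ident_col <- a_chars == b_chars & a_chars != "-"
  win <- (seq_len(n_col) - 1L) %/% as.integer(window_bp)
  ident_win <- as.numeric(tapply(ident_col, win, mean))[win + 1L]
  da <- attr(profile_a, "depth_per_base")
  db <- attr(profile_b, "depth_per_base")
  copies_a_base <- da / (attr(profile_a, "total_read_bp") /
                           attr(profile_a, "genome_size_bp"))
  copies_b_base <- db / (attr(profile_b, "total_read_bp") /
                           attr(profile_b, "genome_size_bp"))
  out <- tibble(
    column = seq_len(n_col),
    pos_a = ifelse(is.na(pos_a), NA_integer_, pos_a - 1L),
    pos_b = ifelse(is.na(pos_b), NA_integer_, pos_b - 1L),
    identity_window = ident_win,
    copies_a = ifelse(is.na(pos_a), NA_real_, copies_a_base[pos_a]),
    copies_b = ifelse(is.na(pos_b), NA_real_, copies_b_base[pos_b])
  )
  structure(out, class = c("profile_comparison", class(out)),
            window_bp = window_bp)
}

#' Plot a copy-number profile
#'
#' @param object a `coverage_profile`.
#' @param ... further `coverage_profile`s to overlay (e.g. a second read
#'   set on the same element).
#' @return a ggplot object: genomic copy number along the element.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  extra <- purrr::keep(list(...), ~ inherits(.x, "coverage_profile"))
  df <- dplyr::bind_rows(lapply(c(list(object), extra), as_tibble))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$window_start + .data$window_end) / 2,
    y = .data$copies, colour = .data$dataset_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position on element (bp)",
                  y = "genomic copy number", colour = "read set")
}

#' Plot a two-element profile comparison
#'
#' @param object a `profile_comparison`.
#' @param ... unused.
#' @return a ggplot object: both copy-number tracks plus the identity track
#'   on the shared alignment coordinate.
#' @method autoplot profile_comparison
#' @export
autoplot.profile_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("copies_a", "copies_b", "identity_window"),
                        names_to = "track", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::labs(x = "alignment column", y = NULL)
}
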