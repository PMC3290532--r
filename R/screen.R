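#' Construct a repeat-family probe panel
#'
#' A panel maps family names to probe sequences — typically conserved
#' domains (reverse-transcriptase or transposase fragments) or tandem-repeat
#' monomers — against which library clones are screened. Several probes may
#' share a family name.
#'
#' @param family character vector of family labels.
#' @param sequence character vector of probe sequences (length >= 20 bp).
#' @return a `probe_panel` tibble with columns `family`, `probe_id`,
#'   `sequence`.
#' @export
probe_panel <- function(family, sequence) {
  if (length(family) == 0) abort("a probe panel cannot be empty")
  if (length(family) != length(sequence)) {
    abort("`family` and `sequence` must have the same length")
  }
  sequence <- toupper(sequence)
  short <- nchar(sequence) < 20
  if (any(short)) {
    abort(sprintf("probe(s) shorter than 20 bp: %s",
                  paste(family[short], collapse = ", ")))
  }
  purrr::walk(sequence, check_alphabet)
  out <- tibble(family = family,
                probe_id = sprintf("%s_probe%d", family,
                                   stats::ave(seq_along(family), family,
                                              FUN = seq_along)),
                sequence = sequence)
  structure(out, class = c("probe_panel", class(out)))
}

#' Best local alignment between two sequences
#'
#' Thin wrapper around affine-gap Smith-Waterman (via
#' `Biostrings::pairwiseAlignment`): returns the maximum local alignment
#' score under the given scheme, the identity over aligned columns, and the
#' aligned span on each sequence (0-based half-open).
#'
#' @param a,b non-empty DNA sequences (character scalars).
#' @param match,mismatch match score and mismatch score.
#' @param gap_open,gap_extend gap opening / extension penalties (positive
#'   costs).
#' @return one-row tibble: `score`, `identity`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `overlap_bp` (aligned span on `a`).
#' @export
#' @examples
#' local_similarity("ACGTACGTACGT", "ACGTACGTACGT")
local_similarity <- function(a, b, match = 1, mismatch = -1,
                             gap_open = 2, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "local", substitutionMatrix = substitution_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  w <- Biostrings::nchar(al)
  tibble(
    score = max(0, Biostrings::score(al)),
    identity = if (w > 0) Biostrings::nmatch(al) / w else 0,
    a_start = BiocGenerics::start(Biostrings::pattern(al)) - 1L,
    a_end = BiocGenerics::end(Biostrings::pattern(al)),
    b_start = BiocGenerics::start(Biostrings::subject(al)) - 1L,
    b_end = BiocGenerics::end(Biostrings::subject(al)),
    overlap_bp = BiocGenerics::width(Biostrings::pattern(al))
  )
}

# Seed prefilter: indices of sequences sharing at least one exact k-mer
# with the probe (or its reverse complement). BLAST-style seeding: at the
# identity thresholds used for screening, true hits share abundant exact
# k-mers, so full alignment is only run on seeded candidates. k = 0
# disables. `by_strand = TRUE` returns separate forward / reverse candidate
# index sets so each candidate is aligned on its seeded strand only.
kmer_candidates <- function(sequences, probe, k, by_strand = FALSE) {
  all_idx <- seq_along(sequences)
  if (k <= 0 || nchar(probe) < k) {
    return(if (by_strand) list(fwd = all_idx, rev = all_idx) else all_idx)
  }
  match_idx <- function(kmers) {
    kmers <- unique(kmers[!grepl("[^ACGT]", kmers)])
    if (length(kmers) == 0) return(all_idx)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(sequences))
    which(lengths(hits) > 0)
  }
  starts <- seq_len(nchar(probe) - k + 1)
  fwd <- match_idx(substring(probe, starts, starts + k - 1))
  rev <- match_idx(substring(revcomp(probe), starts, starts + k - 1))
  if (by_strand) list(fwd = fwd, rev = rev) else sort(union(fwd, rev))
}

# Vectorized local alignment of a set of clones (already on the strand to
# align) against one probe; per-clone score / identity / span on the clone.
align_one_strand <- function(clones, probe, strand, match, mismatch,
                             gap_open, gap_extend) {
  pats <- Biostrings::DNAStringSet(if (strand == "+") clones else revcomp(clones))
  al <- Biostrings::pairwiseAlignment(
    pats, Biostrings::DNAString(probe), type = "local",
    substitutionMatrix = substitution_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  w <- Biostrings::nchar(al)
  tibble(
    score = pmax(0, Biostrings::score(al)),
    identity = ifelse(w > 0, Biostrings::nmatch(al) / w, 0),
    overlap_bp = BiocGenerics::width(Biostrings::pattern(al)),
    strand = strand
  )
}

#' Screen a clone library against a probe panel
#'
#' In-silico counterpart of hybridization-based library screening: a clone
#' is a hit for a family if some probe of that family aligns locally with at
#' least `min_identity` identity over at least `min_overlap_bp` of the
#' clone (both strands searched, as hybridization is strand-agnostic). A
#' clone reaching the thresholds for several families is assigned only to
#' its best-scoring family — one clone, one hit — with ties broken by higher
#' identity, then longer overlap, then panel order. Clones whose runner-up
#' family scores within 5% of the best are flagged `ambiguous`.
#'
#' @param library a `clone_library`, or any tibble with `id` and `sequence`
#'   columns.
#' @param panel a [probe_panel()].
#' @param min_identity minimum identity over aligned columns, in (0.5, 1].
#' @param min_overlap_bp minimum aligned span on the clone, >= 20.
#' @param match,mismatch,gap_open,gap_extend alignment scheme (see
#'   [local_similarity()]).
#' @param seed_length exact k-mer seed length for the candidate prefilter;
#'   0 runs full alignment of every clone against every probe.
#' @return a `screen_result`: list with `assignments` (one row per clone:
#'   `clone_id`, `family` — `NA` when unassigned — `score`, `identity`,
#'   `overlap_bp`, `strand`, `ambiguous`) and `counts` (per panel family:
#'   `family`, `hits`). `tidy()` returns the assignments, `glance()` a
#'   one-row summary, [hit_counts()] the counts.
#' @export
assign_clones <- function(library, panel, min_identity = 0.8,
                          min_overlap_bp = 100, match = 1, mismatch = -1,
                          gap_open = 2, gap_extend = 1, seed_length = 14) {
  if (!inherits(panel, "probe_panel")) {
    if (is.data.frame(panel) && all(c("family", "sequence") %in% names(panel))) {
      panel <- probe_panel(panel$family, panel$sequence)
    } else {
      abort("`panel` must be a probe_panel (or a data frame with family, sequence)")
    }
  }
  if (min_identity <= 0.5 || min_identity > 1) {
    abort("`min_identity` must lie in (0.5, 1]")
  }
  if (min_overlap_bp < 20) abort("`min_overlap_bp` must be at least 20")
  lib <- as_tibble(library)
  families <- unique(panel$family)
  if (nrow(lib) == 0) {
    return(new_screen_result(
      tibble(clone_id = character(), family = character(), score = numeric(),
             identity = numeric(), overlap_bp = integer(), strand = character(),
             ambiguous = logical()),
      tibble(family = families, hits = 0L), panel))
  }
  stopifnot(all(c("id", "sequence") %in% names(lib)))

  # per clone x family best alignment over all of that family's probes
  n <- nrow(lib)
  fam_score <- matrix(0, n, length(families), dimnames = list(NULL, families))
  fam_identity <- matrix(0, n, length(families), dimnames = list(NULL, families))
  fam_overlap <- matrix(0L, n, length(families), dimnames = list(NULL, families))
  fam_strand <- matrix(NA_character_, n, length(families),
                       dimnames = list(NULL, families))
  for (p in seq_len(nrow(panel))) {
    fam <- panel$family[p]
    cand <- kmer_candidates(lib$sequence, panel$sequence[p], seed_length,
                            by_strand = TRUE)
    for (strand in c("+", "-")) {
      idx0 <- if (strand == "+") cand$fwd else cand$rev
      if (length(idx0) == 0) next
      res <- align_one_strand(lib$sequence[idx0], panel$sequence[p], strand,
                              match, mismatch, gap_open, gap_extend)
      better <- res$score > fam_score[idx0, fam] |
        (res$score == fam_score[idx0, fam] &
           res$identity > fam_identity[idx0, fam])
      idx <- idx0[better]
      fam_score[idx, fam] <- res$score[better]
      fam_identity[idx, fam] <- res$identity[better]
      fam_overlap[idx, fam] <- res$overlap_bp[better]
      fam_strand[idx, fam] <- res$strand[better]
    }
  }

  eligible <- fam_identity >= min_identity & fam_overlap >= min_overlap_bp
  # vectorized per-clone argmax under the total order
  # (score, identity, overlap, panel position): iterate families in panel
  # order and replace only on a strict improvement, so earlier panel entries
  # win ties
  best_j <- integer(n)
  second_score <- rep(-Inf, n)
  for (j in seq_along(families)) {
    has_best <- best_j > 0L
    bs <- ifelse(has_best, fam_score[cbind(seq_len(n), pmax(best_j, 1L))], -Inf)
    bi <- ifelse(has_best, fam_identity[cbind(seq_len(n), pmax(best_j, 1L))], -Inf)
    bo <- ifelse(has_best, fam_overlap[cbind(seq_len(n), pmax(best_j, 1L))], -Inf)
    beats <- eligible[, j] &
      (fam_score[, j] > bs |
         (fam_score[, j] == bs &
            (fam_identity[, j] > bi |
               (fam_identity[, j] == bi & fam_overlap[, j] > bo))))
    # displaced best (or non-winning eligible score) feeds the runner-up
    second_score <- pmax(second_score,
                         ifelse(beats, bs, ifelse(eligible[, j],
                                                  fam_score[, j], -Inf)))
    best_j[beats] <- j
  }
  sel <- cbind(seq_len(n), pmax(best_j, 1L))
  found <- best_j > 0L
  assignments <- tibble(
    clone_id = lib$id,
    family = ifelse(found, families[pmax(best_j, 1L)], NA_character_),
    score = ifelse(found, fam_score[sel], NA_real_),
    identity = ifelse(found, fam_identity[sel], NA_real_),
    overlap_bp = ifelse(found, as.integer(fam_overlap[sel]), NA_integer_),
    strand = ifelse(found, fam_strand[sel], NA_character_),
    ambiguous = found & is.finite(second_score) &
      second_score >= 0.95 * ifelse(found, fam_score[sel], Inf)
  )
  counts <- tibble(
    family = families,
    hits = vapply(families,
                  function(f) sum(assignments$family == f, na.rm = TRUE),
                  integer(1), USE.NAMES = FALSE)
  )
  new_screen_result(assignments, counts, panel)
}

new_screen_result <- function(assignments, counts, panel) {
  structure(list(assignments = assignments, counts = counts,
                 families = unique(panel$family)),
            class = "screen_result")
}

#' Per-family hit counts of a screening run
#'
#' @param x a `screen_result`.
#' @return tibble with columns `family` and `hits` (one clone = one hit).
#' @export
hit_counts <- function(x) {
  stopifnot(inherits(x, "screen_result"))
  x$counts
}

#' @rdname assign_clones
#' @param x a `screen_result`.
#' @param ... unused.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$assignments

#' @rdname assign_clones
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    n_clones = nrow(x$assignments),
    n_assigned = sum(!is.na(x$assignments$family)),
    n_ambiguous = sum(x$assignments$ambiguous),
    n_families = length(x$families)
  )
}

#' @export
print.screen_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<screen_result> %d clones, %d assigned across %d families (%d ambiguous)\n",
              g$n_clones, g$n_assigned, g$n_families, g$n_ambiguous))
  print(x$counts)
  invisible(x)
}
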