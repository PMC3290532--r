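#' Build a synthetic genome with known repeat placements
#'
#' Realises a [genome_spec()]: draws a random background sequence, then
#' inserts every family copy at a uniformly sampled, non-overlapping
#' position (rejection sampling, so placement truth intervals are disjoint
#' and recovery tests stay exact). LTR-category copies are inserted either
#' full length or — with probability `solo_ltr_fraction` — as a bare 5'LTR,
#' the solo-LTR relic of intra-element recombination. Tandem families are
#' inserted as arrays of `units_per_array` monomers. Each inserted copy is
#' independently mutated at the family's divergence rate and placed on a
#' random strand.
#'
#' @param spec a [genome_spec()].
#' @return object of class `synthetic_genome`: list with `sequence`
#'   (character scalar of length `genome_size_bp`), `truth` (tibble with
#'   0-based half-open columns `family`, `start`, `end`, `strand`,
#'   `is_solo_ltr`), and the originating `spec`. `tidy()` returns the truth
#'   table.
#' @export
#' @examples
#' fam <- repeat_family("sat", "tandem-satellite",
#'   consensus = strrep("ACGGT", 24), copies = 3, units_per_array = 10)
#' g <- build_genome(genome_spec(10000, fam, seed = 42))
#' tidy(g)
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  G <- spec$genome_size_bp
  with_stage_seed(spec$seed, "build_genome", {
    gc <- spec$background_gc
    chars <- sample(c("A", "C", "G", "T"), G, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    truth <- vector("list", nrow(spec$families))
    placed_start <- integer(0)  # 1-based inclusive
    placed_end <- integer(0)
    for (i in seq_len(nrow(spec$families))) {
      fam <- spec$families[i, ]
      n <- fam$copies
      if (n == 0) {
        truth[[i]] <- empty_truth()
        next
      }
      struct <- fam$structure[[1]]
      is_ltr <- fam$category %in% c("gypsy-LTR", "copia-LTR")
      is_tandem <- fam$category %in% c("tandem-satellite", "microsatellite")
      base_seq <- if (is_tandem) {
        strrep(fam$consensus, fam$units_per_array)
      } else {
        fam$consensus
      }
      solo <- if (is_ltr && fam$solo_ltr_fraction > 0) {
        stats::rbinom(n, 1, fam$solo_ltr_fraction) == 1
      } else {
        rep(FALSE, n)
      }
      ltr_seq <- if (is_ltr) substr(fam$consensus, 1, struct$length[1]) else NA_character_
      starts <- integer(n)
      ends <- integer(n)
      strands <- character(n)
      for (j in seq_len(n)) {
        ins <- if (solo[j]) ltr_seq else base_seq
        ins <- mutate_sequence(ins, fam$divergence)
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") ins <- revcomp(ins)
        len <- nchar(ins)
        ok <- FALSE
        for (attempt in seq_len(2000L)) {
          s <- sample.int(G - len + 1L, 1)  # 1-based start
          e <- s + len - 1L
          if (!any(s <= placed_end & e >= placed_start)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "could not place copy %d of family %s without overlap; genome too full",
            j, fam$name))
        }
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, e)
        chars[s:e] <- strsplit(ins, "", fixed = TRUE)[[1]]
        starts[j] <- s
        ends[j] <- e
        strands[j] <- strand
      }
      truth[[i]] <- tibble(family = fam$name, start = starts - 1L, end = ends,
                           strand = strands, is_solo_ltr = solo)
    }
    structure(
      list(sequence = paste(chars, collapse = ""),
           truth = dplyr::arrange(dplyr::bind_rows(c(list(empty_truth()), truth)),
                                  .data$start),
           spec = spec),
      class = "synthetic_genome"
    )
  })
}

empty_truth <- function() {
  tibble(family = character(), start = integer(), end = integer(),
         strand = character(), is_solo_ltr = logical())
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s bp, %d placed copies from %d famil%s\n",
              format(nchar(x$sequence), big.mark = ","), nrow(x$truth),
              nrow(x$spec$families),
              if (nrow(x$spec$families) == 1) "y" else "ies"))
  invisible(x)
}

#' @rdname build_genome
#' @param x a `synthetic_genome`.
#' @param ... unused.
#' @method tidy synthetic_genome
#' @export
tidy.synthetic_genome <- function(x, ...) x$truth

#' Write placement truth as BED-like TSV
#'
#' Columns: family, start, end (0-based half-open), strand, solo-LTR flag.
#'
#' @param genome a `synthetic_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(genome, path) {
  readr::write_tsv(tidy(genome), path)
  invisible(path)
}
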