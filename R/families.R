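#' Declare a repeat family for the synthetic genome
#'
#' A repeat family is the declarative truth for one class of repetitive
#' element: its consensus sequence, how many copies (or tandem arrays) the
#' genome carries, and how much per-copy divergence to apply at insertion
#' time. LTR-retrotransposon families additionally carry a segment structure
#' (5'LTR, internal domains, 3'LTR) and a solo-LTR fraction: the fraction of
#' insertions that are LTR-only relics of intra-element recombination.
#'
#' @param name family label (e.g. "Retand", "STAR-C").
#' @param category one of `"gypsy-LTR"`, `"copia-LTR"`, `"LINE"`,
#'   `"DNA-transposon"`, `"tandem-satellite"`, `"microsatellite"`.
#' @param consensus consensus sequence; for tandem categories the monomer
#'   unit, for LTR categories the full element (identical LTRs at both ends).
#' @param copies number of inserted copies; for tandem categories the number
#'   of arrays.
#' @param units_per_array tandem categories only: monomer units per array.
#' @param structure LTR categories only: data frame with columns `segment`
#'   and `length` partitioning the consensus in order; first and last
#'   segments must be the identical LTRs. Defaults to a single-segment
#'   structure for non-LTR categories.
#' @param solo_ltr_fraction LTR categories only: expected fraction of copies
#'   inserted as a bare 5'LTR.
#' @param divergence per-base substitution probability in \[0, 0.3\] applied
#'   independently to every inserted copy.
#' @return one-row tibble describing the family (list-column `structure`).
#' @export
#' @examples
#' repeat_family("STAR-C", "tandem-satellite",
#'   consensus = strrep("ACGTT", 4), copies = 10, units_per_array = 25)
repeat_family <- function(name, category, consensus, copies,
                          units_per_array = 1L,
                          structure = NULL,
                          solo_ltr_fraction = 0,
                          divergence = 0) {
  categories <- c("gypsy-LTR", "copia-LTR", "LINE", "DNA-transposon",
                  "tandem-satellite", "microsatellite")
  category <- match.arg(category, categories)
  consensus <- toupper(consensus)
  check_alphabet(consensus, allow = "ACGT")
  if (copies < 0) abort("`copies` must be non-negative")
  if (units_per_array < 1) abort("`units_per_array` must be positive")
  if (divergence < 0 || divergence > 0.3) abort("`divergence` must lie in [0, 0.3]")
  if (solo_ltr_fraction < 0 || solo_ltr_fraction > 1) {
    abort("`solo_ltr_fraction` must lie in [0, 1]")
  }
  is_ltr <- category %in% c("gypsy-LTR", "copia-LTR")
  if (!is_ltr && solo_ltr_fraction > 0) {
    abort("`solo_ltr_fraction` applies to LTR categories only")
  }
  if (is_ltr) {
    if (is.null(structure)) {
      abort(sprintf("LTR family %s needs a `structure` segment table", name))
    }
    structure <- as_tibble(structure)
    stopifnot(all(c("segment", "length") %in% names(structure)))
    if (sum(structure$length) != nchar(consensus)) {
      abort("`structure` lengths must partition the consensus exactly")
    }
    l5 <- structure$length[1]
    l3 <- structure$length[nrow(structure)]
    if (l5 != l3 ||
        substr(consensus, 1, l5) !=
        substr(consensus, nchar(consensus) - l3 + 1, nchar(consensus))) {
      abort(sprintf(
        "LTR family %s: consensus must begin and end with identical LTR segments",
        name))
    }
  } else if (is.null(structure)) {
    structure <- tibble(segment = category, length = nchar(consensus))
  }
  is_tandem <- category %in% c("tandem-satellite", "microsatellite")
  element_bp <- if (is_tandem) nchar(consensus) * units_per_array else nchar(consensus)
  tibble(
    name = name, category = category, consensus = consensus,
    copies = as.integer(copies), units_per_array = as.integer(units_per_array),
    structure = list(structure),
    solo_ltr_fraction = solo_ltr_fraction, divergence = divergence,
    element_bp = as.integer(element_bp)
  )
}

#' Construct a random LTR-retrotransposon consensus
#'
#' Convenience builder for simulation studies: draws random LTR and internal
#' domain sequences and returns the consensus plus its segment structure,
#' with identical LTRs at both ends.
#'
#' @param ltr_bp LTR length in bp.
#' @param internal_bp named integer vector of internal segment lengths in
#'   element order (e.g. `c(gag = 1500, pol = 3000)`).
#' @param gc GC content of the drawn sequence.
#' @param seed integer seed.
#' @return list with elements `consensus` (character) and `structure`
#'   (tibble), ready for [repeat_family()].
#' @export
ltr_consensus <- function(ltr_bp, internal_bp = c(gag = 1000, pol = 2000),
                          gc = 0.4, seed = 1) {
  withr::with_seed(derive_seed(seed, "ltr_consensus"), {
    ltr <- random_dna(ltr_bp, gc)
    internals <- vapply(internal_bp, function(n) random_dna(n, gc), character(1))
  })
  list(
    consensus = paste0(ltr, paste(internals, collapse = ""), ltr),
    structure = tibble(
      segment = c("5'LTR", names(internal_bp), "3'LTR"),
      length = as.integer(c(ltr_bp, internal_bp, ltr_bp))
    )
  )
}

#' Declare a synthetic genome
#'
#' Bundles a genome size, background base composition, and a set of repeat
#' families into the declarative specification consumed by [build_genome()].
#' Total family-occupied bp must fit in the genome.
#'
#' @param genome_size_bp haploid genome size in bp (the 1C value).
#' @param families tibble of [repeat_family()] rows (may be empty).
#' @param background_gc GC fraction of the random background sequence.
#' @param seed integer seed governing genome construction.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(genome_size_bp, families = NULL, background_gc = 0.36,
                        seed = 1) {
  if (genome_size_bp <= 0) abort("`genome_size_bp` must be positive")
  if (background_gc <= 0 || background_gc >= 1) {
    abort("`background_gc` must lie in (0, 1)")
  }
  if (is.null(families)) {
    families <- repeat_family("placeholder", "LINE", "ACGT", 0)[0, ]
  }
  families <- as_tibble(families)
  occupied <- occupied_bp(families)
  if (occupied > genome_size_bp) {
    abort(sprintf(
      "family layout over-full: families occupy %d bp but the genome has %d bp (excess %d bp)",
      occupied, as.integer(genome_size_bp), occupied - as.integer(genome_size_bp)))
  }
  structure(
    list(genome_size_bp = as.integer(genome_size_bp),
         background_gc = background_gc,
         families = families,
         seed = seed),
    class = "genome_spec"
  )
}

# Expected occupied bp if every copy were inserted full length (solo-LTR
# insertions are shorter, so this is the capacity-limiting upper bound).
occupied_bp <- function(families) {
  if (nrow(families) == 0) return(0L)
  as.integer(sum(as.numeric(families$copies) * families$element_bp))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %s bp, GC %.2f, %d famil%s (%s bp occupied), seed %s\n",
              format(x$genome_size_bp, big.mark = ","), x$background_gc,
              nrow(x$families), if (nrow(x$families) == 1) "y" else "ies",
              format(occupied_bp(x$families), big.mark = ","), x$seed))
  invisible(x)
}
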