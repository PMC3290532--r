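# Shared helpers: deterministic RNG scoping, rounding, sequence utilities.

# Derive a deterministic sub-seed for a named pipeline stage so a single
# user-facing seed governs all randomness. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) %% 2147480000 + h) %% 2147483647)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(derive_seed(seed, stage), code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all printed percentages and ratios in this package. Base R's `round()`
#' rounds half to even, which does not reproduce conventionally printed
#' survey tables.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up to `digits`.
#' @export
#' @examples
#' round_half_up(2.805, 2)
#' round_half_up(1.58, 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Reverse complement on plain character vectors (IUPAC-aware); avoids XString
# construction overhead in per-copy simulation loops.
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTRYSWKMBDHVNUacgtryswkmbdhvnu",
           "TGCAYRSWMKVHDBNATgcayrswmkvhdbna",
           intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

# Coerce the sequence-bearing inputs the package accepts (character vector,
# tibble with id/sequence columns, DNAStringSet, synthetic_genome) to a
# named character vector of sequences.
as_sequences <- function(x, arg = "x") {
  if (inherits(x, "synthetic_genome")) {
    out <- stats::setNames(x$sequence, "genome")
  } else if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    out <- stats::setNames(as.character(x), names(x))
  } else if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x))) {
      abort(sprintf("`%s` data frame must have columns `id` and `sequence`", arg))
    }
    out <- stats::setNames(x$sequence, x$id)
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out))) {
      names(out) <- if (length(out) == 1L) "seq" else paste0("seq", seq_along(out))
    }
  } else {
    abort(sprintf("cannot interpret `%s` as DNA sequences", arg))
  }
  toupper(out)
}

check_alphabet <- function(seq, allow = "ACGTNRYSWKMBDHVU-") {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, strsplit(allow, "", fixed = TRUE)[[1]])
  if (length(bad) > 0) {
    abort(sprintf("sequence contains non-IUPAC symbol(s): %s",
                  paste(shQuote(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

substitution_matrix <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

# Apply i.i.d. per-base substitutions at the given rate; used at element
# insertion time to model family divergence.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in pos) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  paste(chars, collapse = "")
}
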