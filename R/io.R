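# FASTA/FASTQ and tabular IO. Parsing is delegated to Biostrings; tables
# are plain TSV with 0-based half-open coordinates throughout.

#' Read sequences from FASTA or FASTQ
#'
#' FASTQ input (detected from the extension or the leading `@`) is read as
#' sequences with qualities ignored. Duplicate record ids are an error;
#' an empty file yields an empty tibble with a warning.
#'
#' @param path input file.
#' @return tibble with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0) {
    warn(sprintf("empty sequence file: %s", path))
    return(tibble(id = character(), sequence = character(), length = integer()))
  }
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE) ||
             startsWith(readChar(path, 1), "@")) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(set))
  if (length(set) == 0) {
    warn(sprintf("empty sequence file: %s", path))
    return(tibble(id = character(), sequence = character(), length = integer()))
  }
  dups <- unique(ids[duplicated(ids)])
  if (length(dups) > 0) {
    abort(sprintf("duplicate record id(s): %s", paste(dups, collapse = ", ")))
  }
  tibble(id = ids, sequence = unname(as.character(set)),
         length = BiocGenerics::width(set))
}

#' Write sequences to FASTA
#'
#' @param x tibble with `id` and `sequence` columns, named character
#'   vector, or `DNAStringSet`.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  seqs <- as_sequences(x)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a probe panel from FASTA
#'
#' The family of each probe is encoded in its record header as
#' `family=NAME` (anywhere in the description); records without the tag use
#' their record id as family.
#'
#' @param path FASTA file of probe sequences.
#' @return a [probe_panel()].
#' @export
read_probe_panel <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort("a probe panel cannot be empty")
  fams <- stringr::str_match(names(set), "family=([^\\s]+)")[, 2]
  ids <- sub("\\s.*$", "", names(set))
  fams[is.na(fams)] <- ids[is.na(fams)]
  probe_panel(fams, as.character(set))
}

#' Write a screening result as TSV
#'
#' Two files: per-clone assignments (`<stem>_assignments.tsv`) and
#' per-family hit counts (`<stem>_counts.tsv`).
#'
#' @param result a `screen_result`.
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_screen_result <- function(result, stem) {
  stopifnot(inherits(result, "screen_result"))
  paths <- paste0(stem, c("_assignments.tsv", "_counts.tsv"))
  readr::write_tsv(tidy(result), paths[1])
  readr::write_tsv(hit_counts(result), paths[2])
  invisible(paths)
}
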