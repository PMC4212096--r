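#' Coerce and validate a genome
#'
#' A genome is represented as a named character vector of upper-case
#' nucleotide sequences (alphabet A/C/G/T/N), one element per contig.
#' Input sequences are case-normalised; a `DNAStringSet` is accepted and
#' converted.
#'
#' @param x Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return Named character vector (upper case) passing all genome
#'   invariants: unique non-empty contig names, non-empty sequences, no
#'   characters outside `{A,C,G,T,N}`.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x) || length(x) == 0L) {
    stopf("genome must be a non-empty named character vector or DNAStringSet")
  }
  nm <- names(x)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stopf("all contigs must have non-empty names")
  }
  if (anyDuplicated(nm)) {
    stopf("duplicated contig name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  x <- toupper(x)
  if (any(!nzchar(x))) stopf("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stopf("contig '%s' contains characters outside {A,C,G,T,N}",
          nm[which(bad)[1L]])
  }
  x
}

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is supported; sequence names are
#' taken up to the first whitespace, matching common aligner conventions.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector as returned by [as_genome()].
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome(seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome Genome (see [as_genome()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), filepath = path, width = width
  )
  invisible(path)
}
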