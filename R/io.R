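# Flat-file interchange: FASTQ via Biostrings, tables as plain TSV,
# summaries as JSON.

#' Write simulated reads as FASTQ
#'
#' Four-line records with a constant placeholder quality (`I`, Phred 40);
#' base-quality modelling is out of scope for the simulator.
#'
#' @param reads `data.frame` with `name` and `seq` (e.g.
#'   `simulate_library(...)$reads`), or an `rrhp_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "rrhp_library")) reads <- reads$reads
  stopifnot(is.data.frame(reads), all(c("name", "seq") %in% names(reads)))
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$name
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  )
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return `data.frame` with `name` (up to first whitespace) and `seq`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(
    name = sub("\\s.*$", "", names(dna)),
    seq = as.character(dna),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write / read a simulation truth table as TSV
#'
#' Columns: contig, pos, strand, hmc_true, mc_true, drawn, surviving,
#' reads.
#'
#' @param truth A `TruthTable` (or the `rrhp_library` holding one).
#' @param path TSV path.
#' @return `path` invisibly ([write_truth()]); a `TruthTable`
#'   ([read_truth()]).
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "rrhp_library")) truth <- truth$truth
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(contig = "character",
                                        strand = "character"),
                         stringsAsFactors = FALSE)
  structure(d, class = c("TruthTable", "data.frame"))
}

#' Write / read an epigenetic profile as TSV
#'
#' Columns: contig, pos, strand, hmc, mc.
#'
#' @param profile An `EpiProfile`.
#' @param path TSV path.
#' @return `path` invisibly ([write_profile()]); an `EpiProfile`
#'   ([read_profile()]).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(contig = "character",
                                        strand = "character"),
                         stringsAsFactors = FALSE)
  structure(d, class = c("EpiProfile", "data.frame"))
}

#' Write / read strand-split site counts as TSV
#'
#' Columns: contig, pos, fwd_reads, rev_reads, total. The write/read
#' pair is idempotent: write, read, write again yields byte-identical
#' files.
#'
#' @param counts A `SiteCounts` data.frame.
#' @param path TSV path.
#' @return `path` invisibly ([write_site_counts()]); a `SiteCounts`
#'   ([read_site_counts()]).
#' @export
write_site_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(contig = "character"),
                         stringsAsFactors = FALSE)
  structure(d, class = c("SiteCounts", "data.frame"))
}

#' Write a library summary as JSON
#'
#' @param summary Named list (e.g. `profile_reads(...)$summary`).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
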