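# BED6 import/export. Coordinates are 0-based half-open on disk and in the
# package's internal frames; rtracklayer handles the 1-based GRanges hop.

#' Write fragments or sites as BED
#'
#' Fragments are written one record per fragment (strand `*`). Sites are
#' written one record per detectable strand, covering the CCGG 4-mer
#' `[pos, pos + 4)` with strand `+` (forward junction) or `-` (reverse
#' junction). Both round-trip through [read_fragments_bed()] /
#' [read_sites_bed()].
#'
#' @param x A `FragmentCatalog` or `SiteCatalog`.
#' @param path Output path (conventionally `.bed`).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) UseMethod("write_intervals")

#' @export
write_intervals.FragmentCatalog <- function(x, path) {
  fr <- x$fragments
  gr <- GenomicRanges::GRanges(
    seqnames = fr$contig,
    ranges = IRanges::IRanges(start = fr$start + 1L, end = fr$end),
    strand = "*"
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @export
write_intervals.SiteCatalog <- function(x, path) {
  if (nrow(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  fwd <- x[x$fwd_detectable, c("contig", "pos"), drop = FALSE]
  rev <- x[x$rev_detectable, c("contig", "pos"), drop = FALSE]
  d <- rbind(cbind(fwd, strand = "+"), cbind(rev, strand = "-"))
  d <- d[order(match(d$contig, unique(x$contig)), d$pos, d$strand), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = d$contig,
    ranges = IRanges::IRanges(start = d$pos + 1L, width = 4L),
    strand = d$strand
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a site catalog from BED
#'
#' Inverse of [write_intervals()] on a `SiteCatalog`: records on the `+`
#' strand set `fwd_detectable`, records on `-` set `rev_detectable`.
#'
#' @param path BED file written by [write_intervals()].
#' @return A `SiteCatalog` data.frame.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  d <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    pos = BiocGenerics::start(gr) - 1L,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  key <- paste(d$contig, d$pos)
  u <- d[!duplicated(key), c("contig", "pos"), drop = FALSE]
  ukey <- paste(u$contig, u$pos)
  u$fwd_detectable <- ukey %in% key[d$strand == "+"]
  u$rev_detectable <- ukey %in% key[d$strand == "-"]
  u <- u[order(match(u$contig, unique(u$contig)), u$pos), , drop = FALSE]
  rownames(u) <- NULL
  structure(u, class = c("SiteCatalog", "data.frame"))
}

#' Read a fragment catalog from BED
#'
#' Rebuilds a `FragmentCatalog` from a fragment BED plus the genome it
#' was derived from. Junction annotations (`left_site`/`right_site`) are
#' recovered by checking the motif at each fragment boundary.
#'
#' @param path BED file written by [write_intervals()] on a catalog.
#' @param genome The genome the fragments came from (see [as_genome()]).
#' @param motif Recognition motif used for the digestion.
#' @param size_range Optional `c(min_len, max_len)` to record on the
#'   catalog (not re-applied).
#' @return A `FragmentCatalog`.
#' @export
read_fragments_bed <- function(path, genome, motif = "CCGG", size_range = NULL) {
  genome <- as_genome(genome)
  gr <- rtracklayer::import(path, format = "BED")
  start <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  contig <- as.character(GenomicRanges::seqnames(gr))
  motif_at <- function(ctg, pos) {
    ok <- !is.na(pos) & pos >= 0L
    out <- rep(NA, length(pos))
    idx <- which(ok)
    if (length(idx)) {
      out[idx] <- substr(genome[ctg[idx]], pos[idx] + 1L,
                         pos[idx] + nchar(motif)) == motif
    }
    out
  }
  left <- start - 1L
  left[!(motif_at(contig, left) %in% TRUE)] <- NA_integer_
  right <- end - 1L
  right[!(motif_at(contig, right) %in% TRUE)] <- NA_integer_
  frags <- data.frame(
    contig = contig, start = start, end = end, length = end - start,
    left_site = left, right_site = right, stringsAsFactors = FALSE
  )
  ord <- order(match(frags$contig, names(genome)), frags$start)
  frags <- frags[ord, , drop = FALSE]
  rownames(frags) <- NULL
  structure(
    list(genome = genome, fragments = frags,
         sites = find_sites(genome, motif),
         size_range = size_range, motif = motif, cut_offset = 1L),
    class = "FragmentCatalog"
  )
}

# Field-count / coordinate sanity check for user-supplied BED, reporting
# the first offending line number (rtracklayer's errors do not).
validate_bed_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "track") || startsWith(ln, "browser") ||
        startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stopf("malformed BED record at line %d: fewer than 3 tab-separated fields", i)
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s < 0L || e < s) {
      stopf("malformed BED record at line %d: bad coordinates '%s' '%s'",
            i, f[2L], f[3L])
    }
  }
  invisible(path)
}

#' Read an annotation BED with category labels
#'
#' The BED name column carries the annotation category (e.g. "intron",
#' "cpg_island"). Malformed records abort with the offending line number.
#'
#' @param path BED file (>= 4 columns; name column required).
#' @return `data.frame` with `contig`, `start`, `end` (0-based half-open)
#'   and `category`.
#' @export
read_annotation_bed <- function(path) {
  validate_bed_file(path)
  gr <- rtracklayer::import(path, format = "BED")
  category <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(NA_character_, length(gr))
  if (anyNA(category)) stopf("annotation BED needs a name (category) column")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    category = category,
    stringsAsFactors = FALSE
  )
}
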