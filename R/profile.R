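#' Test for the CCGG tag at the 5' end of reads
#'
#' A read whose first four bases are exactly `CCGG` (case-insensitive)
#' carries the reconstituted P5-junction tag and reports one 5hmC event.
#' The check is an exact 4-mer match: a sequencing error inside the tag
#' drops the read, which is the conservative behaviour behind tagged
#' percentages below 100.
#'
#' @param seqs Character vector of read sequences in sequencing
#'   orientation.
#' @param tag Junction tag (default `CCGG`).
#' @return Logical vector.
#' @examples
#' has_tag(c("CCGGATTACA", "TCGGATTACA"))
#' @export
has_tag <- function(seqs, tag = "CCGG") {
  if (any(nchar(seqs) < nchar(tag))) {
    stopf("all reads must be at least %d bases long", nchar(tag))
  }
  toupper(substr(seqs, 1L, nchar(tag))) == toupper(tag)
}

#' Assign tagged reads to junction sites
#'
#' A `+` read is assigned to site `s` when its leftmost 0-based position
#' equals `s$pos` (the tag spans the genomic CCGG) and the site is
#' forward-detectable; a `-` read when its rightmost position equals
#' `s$pos + 3` and the site is reverse-detectable. Anything else is
#' unassigned (`NA`), which is a value, not an error.
#'
#' @param alignments `data.frame` with `contig`, `pos` (0-based
#'   leftmost), `strand` (`+`/`-`) and `seq` (used for the read length).
#' @param sites A `SiteCatalog`.
#' @return `alignments` with an added integer column `site_pos` (`NA`
#'   when unassigned).
#' @export
assign_to_site <- function(alignments, sites) {
  stopifnot(inherits(sites, "SiteCatalog"))
  a <- alignments
  rightmost <- a$pos + nchar(a$seq) - 1L
  cand <- ifelse(a$strand == "+", a$pos, rightmost - 3L)
  key <- paste(a$contig, cand)
  skey <- paste(sites$contig, sites$pos)
  idx <- match(key, skey)
  ok <- !is.na(idx) &
    ifelse(a$strand == "+", sites$fwd_detectable[idx],
           sites$rev_detectable[idx])
  a$site_pos <- ifelse(ok, cand, NA_integer_)
  a
}

#' Built-in exact junction matcher
#'
#' Desk-scale aligner for simulated reads: every retained fragment
#' contributes its two junction read sequences (forward junction at the
#' left cut, reverse junction at the right cut) to an index, and each
#' read is compared base-by-base against every junction sequence,
#' truncated to the read length. Among junctions within
#' `max_mismatches`, a unique best match yields an alignment at the
#' corresponding junction; ties at the best mismatch count (e.g. two
#' fragments with identical start sequence) and reads with no junction
#' within the threshold are unmapped. Ungapped by construction.
#'
#' @param reads FASTQ path or `data.frame` with `name`, `seq`.
#' @param fragments A size-selected `FragmentCatalog` from the same
#'   genome the reads came from.
#' @param max_mismatches Maximum substitutions tolerated.
#' @return `data.frame` of aligned reads: `qname`, `contig`, `pos`
#'   (0-based leftmost), `strand`, `seq` (sequencing orientation), one
#'   row per mapped read.
#' @export
builtin_junction_align <- function(reads, fragments, max_mismatches = 0L) {
  stopifnot(inherits(fragments, "FragmentCatalog"))
  if (is.character(reads)) reads <- read_fastq(reads)
  fr <- fragments$fragments
  if (nrow(fr) == 0L) stopf("empty fragment catalog")
  empty <- data.frame(qname = character(0), contig = character(0),
                      pos = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)

  jx <- rbind(
    data.frame(frag_i = which(!is.na(fr$left_site)),
               site = fr$left_site[!is.na(fr$left_site)],
               strand = "+", stringsAsFactors = FALSE),
    data.frame(frag_i = which(!is.na(fr$right_site)),
               site = fr$right_site[!is.na(fr$right_site)],
               strand = "-", stringsAsFactors = FALSE)
  )
  if (nrow(jx) == 0L) return(empty)
  Lmax <- max(nchar(reads$seq))
  jseq <- junction_read_seq(fragments$genome, fr, jx$frag_i, jx$site,
                            jx$strand, Lmax)

  out <- vector("list", 0L)
  for (L in sort(unique(nchar(reads$seq)))) {
    in_grp <- which(nchar(reads$seq) == L)
    mat <- matrix(unlist(strsplit(reads$seq[in_grp], "", fixed = TRUE),
                         use.names = FALSE), nrow = L)
    jtr <- substr(jseq, 1L, L)
    jlen <- nchar(jtr)
    best <- rep(Inf, length(in_grp))
    bestj <- rep(NA_integer_, length(in_grp))
    nbest <- integer(length(in_grp))
    for (j in seq_len(nrow(jx))) {
      jc <- strsplit(jtr[j], "", fixed = TRUE)[[1L]]
      if (jlen[j] == L) {
        mm <- colSums(mat != jc)
      } else {
        mm <- colSums(mat[seq_len(jlen[j]), , drop = FALSE] != jc) +
          (L - jlen[j])   # read overhang past a short junction mismatches
      }
      lt <- mm < best
      eq <- !lt & mm == best
      best[lt] <- mm[lt]; bestj[lt] <- j; nbest[lt] <- 1L
      nbest[eq] <- nbest[eq] + 1L
    }
    hit <- which(best <= max_mismatches & nbest == 1L)
    if (length(hit)) {
      j <- bestj[hit]
      p <- jx$site[j]
      b <- fr$start[jx$frag_i[j]]
      pos0 <- ifelse(jx$strand[j] == "+", p, pmax(b, p + 4L - L))
      out[[length(out) + 1L]] <- data.frame(
        qname = reads$name[in_grp[hit]],
        contig = fr$contig[jx$frag_i[j]],
        pos = as.integer(pos0),
        strand = jx$strand[j],
        seq = reads$seq[in_grp[hit]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load alignments from SAM/BAM
#'
#' Reads are returned in sequencing orientation: sequences of
#' minus-strand records are reverse-complemented back from the aligned
#' orientation SAM stores. Positions are converted to 0-based. Plain-text
#' SAM with records having fewer than 11 fields is tolerated: such lines
#' are skipped with a warning before conversion.
#'
#' @param path `.sam` or `.bam` file.
#' @return List with `alignments` (`data.frame`: `qname`, `contig`,
#'   `pos`, `strand`, `seq`) and `n_total` (all records, including
#'   unmapped).
#' @export
read_alignments_sam <- function(path) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "@")
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    bad <- body & nf < 11L
    if (any(bad)) {
      warning(sprintf("skipping %d malformed SAM record(s) (line %s)",
                      sum(bad), paste(which(bad), collapse = ", ")))
      tmp_sam <- tempfile(fileext = ".sam")
      writeLines(lines[!bad], tmp_sam)
      path <- tmp_sam
    }
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "seq")
    )
  )[[1L]]
  n_total <- length(res$qname)
  mapped <- !bitwAnd(res$flag, 4L) & !is.na(res$pos)
  sq <- as.character(res$seq[mapped])
  minus <- as.character(res$strand[mapped]) == "-"
  if (any(minus)) sq[minus] <- revcomp(sq[minus])
  list(
    alignments = data.frame(
      qname = res$qname[mapped],
      contig = as.character(res$rname[mapped]),
      pos = res$pos[mapped] - 1L,
      strand = as.character(res$strand[mapped]),
      seq = sq,
      stringsAsFactors = FALSE
    ),
    n_total = n_total
  )
}

#' Profile CCGG-tagged reads into strand-specific site counts
#'
#' The core RRHP measurement: every mapped read whose 5' end carries the
#' CCGG tag and whose position lands exactly on a detectable junction is
#' counted once toward that (site, strand). Tagged reads not starting at
#' a cataloged junction go to a diagnostic off-junction tally;
#' untagged/unmapped reads appear only in the summary totals. PCR
#' duplicates are intentionally counted — read number is the display
#' signal.
#'
#' @param x One of: a `.sam`/`.bam` path; a `data.frame` of alignments
#'   (`qname`, `contig`, `pos` 0-based, `strand`, `seq` in sequencing
#'   orientation); a FASTQ path or `data.frame` (`name`, `seq`) — this
#'   last form requires `fragments` and uses
#'   [builtin_junction_align()].
#' @param sites A `SiteCatalog`.
#' @param fragments Optional size-selected `FragmentCatalog`, needed for
#'   the FASTQ input form.
#' @param max_mismatches Passed to [builtin_junction_align()].
#' @param tag Junction tag.
#' @return List with `counts` (a `SiteCounts` data.frame over all
#'   catalog sites: `contig`, `pos`, `fwd_reads`, `rev_reads`, `total`),
#'   `summary` (`total_reads`, `mapped_reads`, `mappability_pct`,
#'   `tagged_reads`, `tagged_pct`, `n_sites`) and `off_junction` (tagged
#'   reads at no cataloged junction).
#' @export
profile_reads <- function(x, sites, fragments = NULL, max_mismatches = 0L,
                          tag = "CCGG") {
  stopifnot(inherits(sites, "SiteCatalog"))
  if (is.character(x) && length(x) == 1L &&
      grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
    sam <- read_alignments_sam(x)
    aln <- sam$alignments
    n_total <- sam$n_total
  } else if (is.data.frame(x) && all(c("contig", "pos", "strand") %in% names(x))) {
    aln <- x
    n_total <- nrow(x)
  } else {
    if (is.null(fragments)) {
      stopf("FASTQ input needs a 'fragments' catalog for the built-in matcher")
    }
    reads <- if (is.character(x)) read_fastq(x) else x
    aln <- builtin_junction_align(reads, fragments, max_mismatches)
    n_total <- nrow(reads)
  }
  n_mapped <- nrow(aln)
  tagged <- if (n_mapped) has_tag(aln$seq, tag) else logical(0)
  n_tagged <- sum(tagged)
  asg <- if (n_mapped) assign_to_site(aln[tagged, , drop = FALSE], sites) else
    data.frame(site_pos = integer(0), contig = character(0),
               strand = character(0))
  assigned <- !is.na(asg$site_pos)
  skey <- paste(sites$contig, sites$pos)
  idx <- match(paste(asg$contig[assigned], asg$site_pos[assigned]), skey)
  fwd <- tabulate(idx[asg$strand[assigned] == "+"], nbins = nrow(sites))
  rev <- tabulate(idx[asg$strand[assigned] == "-"], nbins = nrow(sites))
  counts <- data.frame(
    contig = sites$contig, pos = sites$pos,
    fwd_reads = as.integer(fwd), rev_reads = as.integer(rev),
    total = as.integer(fwd + rev), stringsAsFactors = FALSE
  )
  counts <- structure(counts, class = c("SiteCounts", "data.frame"))
  summary <- list(
    total_reads = n_total,
    mapped_reads = n_mapped,
    mappability_pct = if (n_total) 100 * n_mapped / n_total else 0,
    tagged_reads = n_tagged,
    tagged_pct = if (n_mapped) 100 * n_tagged / n_mapped else 0,
    n_sites = sum(counts$total >= 1L)
  )
  list(counts = counts, summary = summary,
       off_junction = n_tagged - sum(assigned))
}
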