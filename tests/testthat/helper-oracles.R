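# Brute-force oracles, independent of the package's digestion code path:
# plain substring scans and exhaustive fragment membership tests.

oracle_sites <- function(seq, motif = "CCGG") {
  n <- nchar(seq)
  w <- nchar(motif)
  if (n < w) return(integer(0))
  starts <- seq_len(n - w + 1L)
  which(substring(seq, starts, starts + w - 1L) == motif) - 1L  # 0-based
}

oracle_fragments <- function(seq, motif = "CCGG") {
  cuts <- oracle_sites(seq, motif) + 1L
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  start <- c(0L, cuts)
  end <- c(cuts, nchar(seq))
  data.frame(start = start, end = end, length = end - start)
}

# Detectability by exhaustive testing of every motif occurrence against
# every retained fragment.
oracle_detectable <- function(seq, min_len, max_len, motif = "CCGG") {
  fr <- oracle_fragments(seq, motif)
  fr <- fr[fr$length >= min_len & fr$length <= max_len, , drop = FALSE]
  sites <- oracle_sites(seq, motif)
  res <- lapply(sites, function(s) {
    fwd <- any(fr$start == s + 1L)   # a retained fragment begins at the cut
    rev <- any(fr$end == s + 1L)     # a retained fragment ends at the cut
    if (!fwd && !rev) return(NULL)
    data.frame(pos = s, fwd_detectable = fwd, rev_detectable = rev)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(pos = integer(0), fwd_detectable = logical(0),
                      rev_detectable = logical(0))
  }
  out
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Small fixed study system reused across tests: one-contig genome with a
# guaranteed CCGG complement, digested and size-selected.
test_system <- function(contig_length = 20000L, target_sites = 60L,
                        seed = 7L, insert_range = c(40L, 430L)) {
  g <- make_genome(1L, contig_length, target_sites, seed = seed, gc = 0.4)
  cat <- size_select(digest_genome(g), insert_range[1], insert_range[2])
  list(genome = g, catalog = cat, sites = detectable_sites(cat))
}

# Build a SiteCounts data.frame directly (for QC/calibration unit tests).
make_counts <- function(contig, pos, fwd, rev = 0L) {
  fwd <- rep_len(as.integer(fwd), length(pos))
  rev <- rep_len(as.integer(rev), length(pos))
  structure(
    data.frame(contig = rep_len(contig, length(pos)), pos = as.integer(pos),
               fwd_reads = fwd, rev_reads = rev, total = fwd + rev,
               stringsAsFactors = FALSE),
    class = c("SiteCounts", "data.frame")
  )
}

# Build a SiteCatalog data.frame directly.
make_site_catalog <- function(contig, pos, fwd = TRUE, rev = TRUE) {
  structure(
    data.frame(contig = rep_len(contig, length(pos)), pos = as.integer(pos),
               fwd_detectable = rep_len(fwd, length(pos)),
               rev_detectable = rep_len(rev, length(pos)),
               stringsAsFactors = FALSE),
    class = c("SiteCatalog", "data.frame")
  )
}
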