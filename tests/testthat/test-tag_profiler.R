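# Write a minimal SAM file: records are lists/vectors of the 11 mandatory
# fields; header declares one reference.
write_sam <- function(path, contig, len, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, len))
  writeLines(c(hdr, records), path)
}

sam_record <- function(qname, flag, rname, pos1, seq) {
  paste(qname, flag, rname, pos1, 255, paste0(nchar(seq), "M"), "*", 0, 0,
        seq, strrep("I", nchar(seq)), sep = "\t")
}

test_that("the CCGG tag check is an exact case-insensitive 4-mer match", {
  expect_true(has_tag("CCGGATTACA"))
  expect_false(has_tag("TCGGATTACA"))
  expect_false(has_tag("CCGAATTACA"))
  expect_equal(has_tag(c("ccggTT", "CcGgAA", "CCGG")), c(TRUE, TRUE, TRUE))
  expect_error(has_tag(c("CCGGAA", "CCG")), "4 bases")
})

test_that("reads are assigned to junctions by exact coordinate arithmetic", {
  sites <- make_site_catalog("c1", 100L)
  aln <- data.frame(
    contig = "c1",
    pos = c(100L, 101L, 84L),
    strand = c("+", "+", "-"),
    seq = c(strrep("A", 30), strrep("A", 30), strrep("A", 20)),
    stringsAsFactors = FALSE
  )
  got <- assign_to_site(aln, sites)
  expect_equal(got$site_pos, c(100L, NA_integer_, 100L))
  # detectability gates assignment per strand
  fwd_only <- make_site_catalog("c1", 100L, fwd = TRUE, rev = FALSE)
  got2 <- assign_to_site(aln, fwd_only)
  expect_equal(got2$site_pos, c(100L, NA_integer_, NA_integer_))
})

test_that("the built-in junction matcher maps error-free reads to their truth", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  lib <- simulate_library(sys$genome, prof,
                          library_config(n_molecules_per_fragment = 40,
                                         seed = 21))
  aln <- builtin_junction_align(lib$reads, sys$catalog, max_mismatches = 0)
  expect_equal(nrow(aln), nrow(lib$reads))
  # read names carry contig|pos|strand truth
  truth <- strsplit(aln$qname, "|", fixed = TRUE)
  expect_equal(aln$contig, vapply(truth, `[[`, "", 1))
  tpos <- as.integer(vapply(truth, `[[`, "", 2))
  tstrand <- vapply(truth, `[[`, "", 3)
  expect_equal(aln$strand, tstrand)
  expect_equal(ifelse(aln$strand == "+", aln$pos,
                      aln$pos + nchar(aln$seq) - 1L - 3L), tpos)
})

test_that("mismatch tolerance and ambiguity rules behave as specified", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  lib <- simulate_library(sys$genome, prof,
                          library_config(n_molecules_per_fragment = 5,
                                         seed = 22))
  r <- lib$reads[1, , drop = FALSE]
  substr(r$seq, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r$seq, 10, 10))[1]
  expect_equal(nrow(builtin_junction_align(r, sys$catalog, 0)), 0L)
  expect_equal(nrow(builtin_junction_align(r, sys$catalog, 1)), 1L)

  # two fragments with identical start sequence: ambiguous, unmapped
  spacer <- "ATTAGACCTGAATTAGACCTGA"
  g <- c(ctg = paste0(strrep("A", 10), "CCGG", spacer, "CCGG", spacer,
                      "CCGG", strrep("A", 10)))
  cat2 <- size_select(digest_genome(g), 5, 100)
  dup_read <- data.frame(name = "r1",
                         seq = paste0("CCGG", substr(spacer, 1, 16)),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(builtin_junction_align(dup_read, cat2, 0)), 0L)

  empty_cat <- size_select(digest_genome(c(ctg = "ACCGGTACCGGT")), 1, 1)
  expect_error(builtin_junction_align(dup_read, empty_cat), "empty")
})

test_that("profiling reproduces the simulator truth exactly without errors", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  lib <- simulate_library(sys$genome, prof,
                          library_config(n_molecules_per_fragment = 40,
                                         pcr_duplicate_mean = 1.4, seed = 23))
  pr <- profile_reads(lib$reads, sys$sites, fragments = sys$catalog)
  tr <- lib$truth
  m <- merge(tr, pr$counts, by = c("contig", "pos"))
  expect_equal(m$reads[m$strand == "+"], m$fwd_reads[m$strand == "+"])
  expect_equal(m$reads[m$strand == "-"], m$rev_reads[m$strand == "-"])
  # conservation: tagged = assigned + off-junction
  expect_equal(pr$summary$tagged_reads,
               sum(pr$counts$total) + pr$off_junction)
  expect_equal(pr$summary$n_sites, sum(pr$counts$total >= 1L))
  # order independence
  perm <- lib$reads[rev(seq_len(nrow(lib$reads))), ]
  pr2 <- profile_reads(perm, sys$sites, fragments = sys$catalog)
  expect_equal(pr2$counts, pr$counts)
})

test_that("zero reads produce an all-zero summary, not an error", {
  sys <- test_system(contig_length = 5000L, target_sites = 15L)
  none <- data.frame(name = character(0), seq = character(0),
                     stringsAsFactors = FALSE)
  pr <- profile_reads(none, sys$sites, fragments = sys$catalog)
  expect_equal(pr$summary$total_reads, 0L)
  expect_equal(pr$summary$mappability_pct, 0)
  expect_equal(pr$summary$tagged_pct, 0)
  expect_equal(pr$summary$n_sites, 0L)
  expect_true(all(pr$counts$total == 0L))
})

test_that("SAM input is counted with mappability and tag percentages", {
  g <- c(c1 = paste0(strrep("A", 30), "CCGG", strrep("T", 46), "CCGG",
                     strrep("A", 30)))
  cat2 <- size_select(digest_genome(g), 5, 200)
  sites <- detectable_sites(cat2)
  p <- 30L  # left site, 0-based
  plus_seq <- substr(g, p + 1L, p + 20L)              # CCGG + fragment, fwd
  q <- 80L  # right site of the middle fragment
  recs <- c(
    vapply(1:7, function(i) sam_record(paste0("p", i), 0, "c1", p + 1L,
                                       plus_seq), ""),
    sam_record("m1", 16, "c1", q + 4L - 15L, substr(g, q + 4L - 15L, q + 4L)),
    sam_record("untag", 0, "c1", p + 2L, substr(g, p + 2L, p + 21L)),
    paste("un", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 20),
          strrep("I", 20), sep = "\t")
  )
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, "c1", nchar(g), recs)
  pr <- profile_reads(sam, sites)
  expect_equal(pr$summary$total_reads, 10L)
  expect_equal(pr$summary$mapped_reads, 9L)
  expect_equal(pr$summary$mappability_pct, 90)
  expect_equal(pr$summary$tagged_reads, 8L)  # 7 fwd + 1 rev; off-start untagged
  expect_equal(pr$counts$fwd_reads[pr$counts$pos == p], 7L)
  expect_equal(pr$counts$rev_reads[pr$counts$pos == q], 1L)

  # malformed record: skipped with a warning, not fatal
  writeLines(c(readLines(sam), "broken\trecord"), sam)
  expect_warning(pr2 <- profile_reads(sam, sites), "malformed")
  expect_equal(pr2$summary$total_reads, 10L)
})

test_that("site-count TSV writing is idempotent", {
  counts <- make_counts("c1", c(10L, 50L, 90L), fwd = c(3L, 0L, 5L),
                        rev = c(1L, 2L, 0L))
  f1 <- tempfile(); f2 <- tempfile()
  write_site_counts(counts, f1)
  back <- read_site_counts(f1)
  expect_equal(as.data.frame(back), as.data.frame(counts))
  write_site_counts(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
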