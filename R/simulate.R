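#' Generate a random test genome with a controllable CCGG density
#'
#' Draws i.i.d. nucleotides at the given GC content, then plants extra
#' copies of the motif at random positions until each contig carries at
#' least `target_site_count` occurrences. Byte-identical output for a
#' given seed.
#'
#' @param n_contigs Number of contigs (named `chr1`, `chr2`, ...).
#' @param contig_length Length of every contig in bp.
#' @param target_site_count Minimum motif occurrences per contig
#'   (0 = plain random sequence).
#' @param seed Integer seed.
#' @param gc GC content of the random background in `[0, 1]`.
#' @param motif Motif to plant (default MspI `CCGG`).
#' @return A genome as returned by [as_genome()].
#' @export
make_genome <- function(n_contigs = 1L, contig_length, target_site_count = 0L,
                        seed, gc = 0.5, motif = "CCGG") {
  n_contigs <- as.integer(n_contigs)
  contig_length <- as.integer(contig_length)
  target_site_count <- as.integer(target_site_count)
  if (n_contigs < 1L || contig_length < 1L || target_site_count < 0L) {
    stopf("n_contigs, contig_length must be positive; target_site_count >= 0")
  }
  w <- nchar(motif)
  if (target_site_count * w > contig_length) {
    stopf("target_site_count %d infeasible for contig_length %d",
          target_site_count, contig_length)
  }
  if (gc < 0 || gc > 1) stopf("gc must be in [0, 1]")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      s <- paste(sample(names(p), contig_length, replace = TRUE, prob = p),
                 collapse = "")
      for (iter in 1:25) {
        n_have <- nrow(find_sites(c(ctg = s), motif))
        if (n_have >= target_site_count) break
        at <- sample.int(contig_length - w + 1L, target_site_count - n_have)
        for (a in at) substr(s, a, a + w - 1L) <- motif
      }
      if (nrow(find_sites(c(ctg = s), motif)) < target_site_count) {
        stopf("could not reach target_site_count %d on a %d bp contig",
              target_site_count, contig_length)
      }
      s
    }, character(1))
    as_genome(stats::setNames(seqs, paste0("chr", seq_len(n_contigs))))
  })
}

#' Draw a per-site per-strand modification profile
#'
#' Ground truth for the simulator: for every detectable (site, strand)
#' pair, the 5hmC fraction is 0 with probability `zero_hmc_fraction` and
#' otherwise Beta-distributed; the 5mC fraction is an independent Beta
#' draw, clipped so `hmc + mc <= 1`. The zero-inflation plus a
#' low-mean Beta reproduces the heavy skew toward weakly
#' hydroxymethylated sites seen in brain RRHP coverage distributions.
#'
#' @param sites A `SiteCatalog` from [detectable_sites()].
#' @param hmc_beta Numeric `c(shape1, shape2)` for the 5hmC Beta
#'   component.
#' @param mc_beta Numeric `c(shape1, shape2)` for the 5mC Beta.
#' @param zero_hmc_fraction Probability of exactly zero 5hmC at a pair.
#' @param seed Integer seed.
#' @return An `EpiProfile` data.frame: `contig`, `pos`, `strand`, `hmc`,
#'   `mc`, one row per detectable (site, strand) pair.
#' @export
make_profile <- function(sites, hmc_beta = c(2, 5), mc_beta = c(5, 2),
                         zero_hmc_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(sites, "SiteCatalog"))
  if (length(hmc_beta) != 2L || any(hmc_beta <= 0) ||
      length(mc_beta) != 2L || any(mc_beta <= 0)) {
    stopf("Beta parameters must be two positive shapes")
  }
  if (zero_hmc_fraction < 0 || zero_hmc_fraction > 1) {
    stopf("zero_hmc_fraction must be in [0, 1]")
  }
  pairs <- site_strand_pairs(sites)
  n <- nrow(pairs)
  with_seed(seed, {
    hmc <- stats::rbeta(n, hmc_beta[1], hmc_beta[2])
    hmc[stats::runif(n) < zero_hmc_fraction] <- 0
    mc <- stats::rbeta(n, mc_beta[1], mc_beta[2])
    mc <- pmin(mc, 1 - hmc)
    out <- cbind(pairs, hmc = hmc, mc = mc)
    structure(out, class = c("EpiProfile", "data.frame"))
  })
}

# Expand a SiteCatalog to its detectable (site, strand) rows.
site_strand_pairs <- function(sites) {
  fwd <- sites[sites$fwd_detectable, c("contig", "pos"), drop = FALSE]
  rev <- sites[sites$rev_detectable, c("contig", "pos"), drop = FALSE]
  d <- rbind(cbind(fwd, strand = "+", stringsAsFactors = FALSE),
             cbind(rev, strand = "-", stringsAsFactors = FALSE))
  d <- d[order(match(d$contig, unique(sites$contig)), d$pos, d$strand), ,
         drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Library simulation parameters
#'
#' Bundles and validates the knobs of the molecule-level library
#' simulation. Defaults encode the reference workflow: two adapter
#' species at equal molarity (`hetero_adapter_prob = 0.5`), 40-430 bp
#' insert selection, 50 bp single-end reads, complete second digestion,
#' no PCR over-duplication and no sequencing error.
#'
#' @param n_molecules_per_fragment Molecules sampled per retained
#'   fragment.
#' @param beta_gt Glucosylation step on (`TRUE`) or omitted — the
#'   negative-control library.
#' @param second_enzyme `"MspI"` (blocked only by glucosyl-5hmC) or
#'   `"HpaII"` (blocked by 5mC, 5hmC or glucosyl-5hmC).
#' @param digestion_failure_rate Probability that a cleavable molecule
#'   escapes the second digestion (incomplete-digestion background).
#' @param hetero_adapter_prob Probability a molecule is
#'   hetero-adapterized (P5/P7); homo-adapterized molecules hairpin and
#'   never amplify.
#' @param insert_range `c(min, max)` insert size selection in bp.
#' @param read_length Read length in bp (>= 4: must contain the tag).
#' @param seq_error_rate Per-base substitution error rate.
#' @param pcr_duplicate_mean Mean number of reads per surviving molecule
#'   (>= 1); duplicates follow 1 + Geometric(1/mean).
#' @param seed Integer seed driving all molecule-level randomness.
#' @return A validated `LibraryConfig` list.
#' @export
library_config <- function(n_molecules_per_fragment = 100L,
                           beta_gt = TRUE,
                           second_enzyme = c("MspI", "HpaII"),
                           digestion_failure_rate = 0,
                           hetero_adapter_prob = 0.5,
                           insert_range = c(40L, 430L),
                           read_length = 50L,
                           seq_error_rate = 0,
                           pcr_duplicate_mean = 1,
                           seed = 1L) {
  second_enzyme <- match.arg(second_enzyme)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stopf("'%s' must be a single value in [0, 1]", nm)
  }
  chk01(digestion_failure_rate, "digestion_failure_rate")
  chk01(hetero_adapter_prob, "hetero_adapter_prob")
  chk01(seq_error_rate, "seq_error_rate")
  n_molecules_per_fragment <- as.integer(n_molecules_per_fragment)
  read_length <- as.integer(read_length)
  if (n_molecules_per_fragment < 1L) stopf("need >= 1 molecule per fragment")
  if (read_length < 4L) stopf("read_length must be >= 4 (the CCGG tag)")
  if (length(insert_range) != 2L || insert_range[1] < 1 ||
      insert_range[1] > insert_range[2]) {
    stopf("insert_range must be c(min, max) with 1 <= min <= max")
  }
  if (!is.numeric(pcr_duplicate_mean) || pcr_duplicate_mean < 1) {
    stopf("pcr_duplicate_mean must be >= 1")
  }
  structure(
    list(n_molecules_per_fragment = n_molecules_per_fragment,
         beta_gt = isTRUE(beta_gt),
         second_enzyme = second_enzyme,
         digestion_failure_rate = digestion_failure_rate,
         hetero_adapter_prob = hetero_adapter_prob,
         insert_range = as.integer(insert_range),
         read_length = read_length,
         seq_error_rate = seq_error_rate,
         pcr_duplicate_mean = pcr_duplicate_mean,
         seed = as.integer(seed)),
    class = "LibraryConfig"
  )
}

#' Simulate an RRHP sequencing library
#'
#' Molecule-level simulation of the positive-display workflow. For every
#' size-selected MspI fragment, `n_molecules_per_fragment` molecules are
#' adapterized: a molecule is hetero-adapterized (P5/P7) with probability
#' `hetero_adapter_prob`, the P5 end falling on either fragment end with
#' equal probability; homo-adapterized molecules hairpin and emit
#' nothing, as does a P5 end at a contig boundary (no junction). The
#' cytosine state at the P5-junction CpG on the molecule's read strand is
#' drawn from the profile (5hmC / 5mC / unmodified). With glucosylation
#' on, 5hmC becomes glucosyl-5hmC. The second digestion then removes the
#' molecule unless the junction is protected — MspI is blocked only by
#' glucosyl-5hmC, HpaII by 5mC, 5hmC or glucosyl-5hmC — except that a
#' cleavable molecule escapes with probability `digestion_failure_rate`.
#' Survivors are PCR-duplicated (1 + Geometric, mean
#' `pcr_duplicate_mean`) and each copy emits one read: the reconstituted
#' CCGG followed by the fragment sequence from the junction, on the
#' molecule's read strand, truncated to `read_length`, with independent
#' per-base substitution errors.
#'
#' All molecule-level randomness is drawn up front in a fixed order, so
#' two runs sharing a seed but differing in `second_enzyme` or `beta_gt`
#' see identical molecule draws — survivors under MspI+glucosylation are
#' then a subset of survivors under HpaII.
#'
#' @param genome Genome (see [as_genome()]).
#' @param profile `EpiProfile` matching
#'   `detectable_sites(size_select(digest_genome(genome), insert_range))`.
#' @param config A [library_config()].
#' @return An `rrhp_library` list: `reads` (data.frame `name`, `seq`;
#'   names encode `contig|pos|strand|molecule|copy`), `truth` (the
#'   `TruthTable`: per (site, strand) true fractions, molecules drawn,
#'   surviving, reads emitted), `sites`, `catalog`, `config`.
#' @export
simulate_library <- function(genome, profile, config) {
  stopifnot(inherits(config, "LibraryConfig"))
  genome <- as_genome(genome)
  catalog <- size_select(digest_genome(genome),
                         config$insert_range[1], config$insert_range[2])
  sites <- detectable_sites(catalog)
  pairs <- site_strand_pairs(sites)
  pkey <- paste(pairs$contig, pairs$pos, pairs$strand)
  fkey <- paste(profile$contig, profile$pos, profile$strand)
  if (nrow(profile) != nrow(pairs) || !setequal(pkey, fkey)) {
    stopf("profile does not cover exactly the detectable (site, strand) pairs %s",
          "of this genome and insert range")
  }
  profile <- profile[match(pkey, fkey), , drop = FALSE]

  fr <- catalog$fragments
  nf <- nrow(fr)
  nm <- config$n_molecules_per_fragment
  M <- nf * nm
  if (M == 0L) stopf("no fragments retained; nothing to simulate")
  frag <- rep(seq_len(nf), each = nm)

  res <- with_seed(config$seed, {
    u_het <- stats::runif(M)
    u_end <- stats::runif(M)
    u_state <- stats::runif(M)
    u_escape <- stats::runif(M)
    u_pcr <- stats::runif(M)

    hetero <- u_het < config$hetero_adapter_prob
    p5_left <- u_end < 0.5
    site_pos <- ifelse(p5_left, fr$left_site[frag], fr$right_site[frag])
    strand <- ifelse(p5_left, "+", "-")
    drawn <- hetero & !is.na(site_pos)

    pair_idx <- rep(NA_integer_, M)
    pair_idx[drawn] <- match(
      paste(fr$contig[frag[drawn]], site_pos[drawn], strand[drawn]), pkey)

    hmc <- profile$hmc[pair_idx]
    mc <- profile$mc[pair_idx]
    state <- rep(NA_character_, M)
    state[drawn] <- ifelse(u_state[drawn] < hmc[drawn], "hmc",
                    ifelse(u_state[drawn] < hmc[drawn] + mc[drawn], "mc",
                           "unmod"))

    protected <- if (config$second_enzyme == "MspI") {
      config$beta_gt & state == "hmc"
    } else {
      state %in% c("mc", "hmc") & drawn
    }
    protected[!drawn] <- FALSE
    survive <- drawn &
      (protected | u_escape < config$digestion_failure_rate)

    copies <- integer(M)
    if (config$pcr_duplicate_mean > 1) {
      copies[survive] <- 1L +
        stats::qgeom(u_pcr[survive], prob = 1 / config$pcr_duplicate_mean)
    } else {
      copies[survive] <- 1L
    }

    sidx <- which(survive)
    ridx <- rep(sidx, copies[sidx])              # one row per emitted read
    copy_no <- sequence(copies[sidx])
    sq <- junction_read_seq(
      genome, fr, frag[ridx], site_pos[ridx], strand[ridx],
      config$read_length
    )
    if (config$seq_error_rate > 0 && length(sq)) {
      sq <- apply_seq_errors(sq, config$seq_error_rate)
    }
    list(drawn = drawn, survive = survive, copies = copies,
         pair_idx = pair_idx, sidx = sidx, ridx = ridx, copy_no = copy_no,
         sq = sq)
  })

  site_pos_read <- pairs$pos[res$pair_idx[res$ridx]]
  strand_read <- pairs$strand[res$pair_idx[res$ridx]]
  contig_read <- pairs$contig[res$pair_idx[res$ridx]]
  nm_reads <- sprintf("%s|%d|%s|m%d|c%d", contig_read, site_pos_read,
                      strand_read, res$ridx, res$copy_no)

  npair <- nrow(pairs)
  truth <- data.frame(
    contig = pairs$contig, pos = pairs$pos, strand = pairs$strand,
    hmc_true = profile$hmc, mc_true = profile$mc,
    drawn = tabulate(res$pair_idx[res$drawn], nbins = npair),
    surviving = tabulate(res$pair_idx[res$survive], nbins = npair),
    reads = as.integer(tabulate(res$pair_idx[res$ridx], nbins = npair)),
    stringsAsFactors = FALSE
  )

  structure(
    list(reads = data.frame(name = nm_reads, seq = res$sq,
                            stringsAsFactors = FALSE),
         truth = structure(truth, class = c("TruthTable", "data.frame")),
         sites = sites, catalog = catalog, config = config),
    class = "rrhp_library"
  )
}

# Read sequence emitted from the P5 junction of a fragment, in sequencing
# orientation. `+` reads start at the genomic CCGG of the left junction;
# `-` reads are the reverse complement ending at the right junction's
# CCGG (read rightmost genomic base = site pos + 3).
junction_read_seq <- function(genome, fr, frag_i, site_pos, strand, read_length) {
  ctg <- fr$contig[frag_i]
  seqs <- genome[ctg]
  out <- character(length(frag_i))
  plus <- strand == "+"
  if (any(plus)) {
    s <- site_pos[plus]
    e <- fr$end[frag_i[plus]]
    out[plus] <- substr(seqs[plus], s + 1L, pmin(s + read_length, e))
  }
  if (any(!plus)) {
    p <- site_pos[!plus]
    b <- fr$start[frag_i[!plus]]
    lo <- pmax(b + 1L, p + 5L - read_length)
    out[!plus] <- revcomp(substr(seqs[!plus], lo, p + 4L))
  }
  unname(out)
}

# Independent per-base substitution errors at the given rate.
apply_seq_errors <- function(sq, rate) {
  chars <- strsplit(sq, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G"))
    pick <- 1L + as.integer(floor(stats::runif(length(hit)) * 3))
    pick[pick > 3L] <- 3L
    flat[hit] <- vapply(seq_along(hit), function(k) {
      alt[[flat[hit[k]]]][pick[k]]
    }, character(1))
    read_of <- rep(seq_along(lens), lens)
    changed <- unique(read_of[hit])
    pieces <- split(flat, read_of)
    sq[changed] <- vapply(pieces[as.character(changed)], paste,
                          character(1), collapse = "")
  }
  sq
}

#' @export
print.rrhp_library <- function(x, ...) {
  cat(sprintf(
    "rrhp_library: %d read(s) from %d detectable (site, strand) pair(s) [%s%s]\n",
    nrow(x$reads), nrow(x$truth), x$config$second_enzyme,
    if (x$config$beta_gt) " +betaGT" else " -betaGT"
  ))
  invisible(x)
}
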