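#' Read RRBS methylation calls from TSV
#'
#' Minimal dialect of common methylation-call exports: four tab-separated
#' columns `contig`, `pos` (0-based position of the CpG cytosine),
#' `coverage`, `meth_fraction`, with a header line.
#'
#' @param path TSV path.
#' @return `data.frame` of RRBS calls.
#' @export
read_rrbs_calls <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(contig = "character"),
                         stringsAsFactors = FALSE)
  need <- c("contig", "pos", "coverage", "meth_fraction")
  if (!all(need %in% names(d))) {
    stopf("RRBS TSV needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(d$meth_fraction < 0 | d$meth_fraction > 1, na.rm = TRUE)) {
    stopf("meth_fraction outside [0, 1]")
  }
  d
}

# Map RRBS CpG cytosine positions to CCGG site positions: the forward
# CpG cytosine sits at site pos + 1, the reverse at site pos + 2.
match_cpg_to_site <- function(calls, sites) {
  skey <- paste(sites$contig, sites$pos)
  f <- match(paste(calls$contig, calls$pos - 1L), skey)   # forward C
  r <- match(paste(calls$contig, calls$pos - 2L), skey)   # reverse C
  idx <- ifelse(!is.na(f), f, r)
  idx
}

#' False-call rate table from an RRBS cross-check
#'
#' RRBS and RRHP share MspI fragmentation, so a CpG with deep RRBS
#' coverage and zero methylation should show no RRHP reads; tagged reads
#' at such sites are false calls. Among qualifying sites — RRBS coverage
#' strictly greater than `min_coverage`, methylation at most `max_meth`,
#' and the CpG inside a detectable CCGG site — `N_i` counts sites with
#' RRHP total >= i reads and the error rate is `E_i = N_i / N`. Rows are
#' indexed by the read cutoff i, so `E_i` is non-increasing by
#' construction.
#'
#' @param counts RRHP `SiteCounts`.
#' @param rrbs RRBS calls (`data.frame` as [read_rrbs_calls()]).
#' @param sites `SiteCatalog` of potential RRHP sites.
#' @param min_coverage Qualify when RRBS coverage is strictly greater.
#' @param max_meth Qualify when methylation fraction is at most this.
#' @param max_cutoff Largest read cutoff tabulated.
#' @return An `ErrorTable` data.frame: `cutoff`, `n_i`, `e_i`, with
#'   attribute `N` (number of qualifying sites).
#' @export
false_call_table <- function(counts, rrbs, sites, min_coverage = 50L,
                             max_meth = 0, max_cutoff = 10L) {
  stopifnot(inherits(sites, "SiteCatalog"))
  qual <- rrbs$coverage > min_coverage & rrbs$meth_fraction <= max_meth
  idx <- match_cpg_to_site(rrbs[qual, , drop = FALSE], sites)
  site_idx <- unique(idx[!is.na(idx)])
  N <- length(site_idx)
  if (N == 0L) stopf("no qualifying sites: calibration impossible")
  ckey <- paste(counts$contig, counts$pos)
  skey <- paste(sites$contig[site_idx], sites$pos[site_idx])
  tot <- counts$total[match(skey, ckey)]
  tot[is.na(tot)] <- 0L
  cutoff <- seq_len(max_cutoff)
  n_i <- vapply(cutoff, function(i) sum(tot >= i), integer(1))
  structure(
    data.frame(cutoff = cutoff, n_i = n_i, e_i = n_i / N),
    N = N, class = c("ErrorTable", "data.frame")
  )
}

#' Minimal read cutoff for a target error rate
#'
#' @param table An `ErrorTable` from [false_call_table()].
#' @param threshold Target error rate; the smallest cutoff with
#'   `E_i < threshold` is returned.
#' @return Integer cutoff, or `NA_integer_` when no tabulated cutoff
#'   reaches the target.
#' @export
min_cutoff <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "ErrorTable"))
  ok <- which(table$e_i < threshold)
  if (!length(ok)) return(NA_integer_)
  table$cutoff[ok[1L]]
}

#' glucMS-qPCR 5hmC percentage
#'
#' Locus-specific 5hmC quantitation from three Ct values: undigested
#' input (`Intact`), MspI-digested after mock glucosylation
#' (`Digested -`) and MspI-digested after glucosylation (`Digested +`).
#' The 5hmC percentage is
#' `100 * (Digested- - Digested+) / (Digested- - Intact)`: full glucosyl
#' protection brings the `Digested +` Ct down to the intact sample
#' (100%), no protection leaves it at the mock digestion (0%). Ct noise
#' can push the raw value outside `[0, 100]`, so the clamped value is
#' reported alongside the raw one; the result is invariant under adding
#' a constant to all three Cts. A `Digested -` Ct below the intact Ct is
#' chemically implausible (digestion removes template) and is flagged
#' with a warning, not an error.
#'
#' @param ct_intact,ct_digested_minus,ct_digested_plus Ct values
#'   (vectors recycle).
#' @return `data.frame` with `raw` and `percent` (clamped to
#'   `[0, 100]`).
#' @export
glucms_percent <- function(ct_intact, ct_digested_minus, ct_digested_plus) {
  denom <- ct_digested_minus - ct_intact
  if (any(denom == 0)) {
    stopf("Digested- and Intact Ct are equal: 5hmC%% undefined")
  }
  if (any(denom < 0)) {
    warning("Digested- Ct below Intact Ct: implausible measurement, check inputs")
  }
  raw <- 100 * (ct_digested_minus - ct_digested_plus) / denom
  data.frame(raw = raw, percent = pmin(pmax(raw, 0), 100))
}

#' Read a glucMS-qPCR Ct table
#'
#' TSV with columns `locus`, `ct_intact`, `ct_digested_minus`,
#' `ct_digested_plus` (triplicates are averaged upstream).
#'
#' @param path TSV path.
#' @return `data.frame` of Ct measurements.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("locus", "ct_intact", "ct_digested_minus", "ct_digested_plus")
  if (!all(need %in% names(d))) {
    stopf("Ct TSV needs columns: %s", paste(need, collapse = ", "))
  }
  d
}

#' Annotation-category summary of profiled sites
#'
#' Overlaps detected sites (the CCGG 4-mer `[pos, pos + 4)`) with
#' labelled annotation intervals. Both directions are reported: the
#' fraction of sites falling in each category (a site may count in
#' several categories) and the fraction of each category's intervals
#' covered by at least one site. Results do not depend on record order.
#'
#' @param counts `SiteCounts`; sites with `total >= 1` are annotated.
#' @param annotation BED path (name column = category) or `data.frame`
#'   with `contig`, `start`, `end` (0-based half-open), `category`.
#' @return `data.frame` per category: `category`, `n_sites`,
#'   `frac_sites`, `n_intervals`, `n_intervals_covered`,
#'   `frac_intervals_covered`.
#' @export
annotate_sites <- function(counts, annotation) {
  if (is.character(annotation)) annotation <- read_annotation_bed(annotation)
  stopifnot(all(c("contig", "start", "end", "category") %in% names(annotation)))
  d <- counts[counts$total >= 1L, , drop = FALSE]
  site_gr <- GenomicRanges::GRanges(
    d$contig, IRanges::IRanges(start = d$pos + 1L, width = 4L))
  ann_gr <- GenomicRanges::GRanges(
    annotation$contig,
    IRanges::IRanges(start = annotation$start + 1L, end = annotation$end))
  hits <- GenomicRanges::findOverlaps(site_gr, ann_gr)
  cats <- sort(unique(annotation$category))
  n_sites_tot <- length(site_gr)
  out <- lapply(cats, function(cc) {
    in_cat <- which(annotation$category == cc)
    h <- hits[S4Vectors::subjectHits(hits) %in% in_cat]
    data.frame(
      category = cc,
      n_sites = length(unique(S4Vectors::queryHits(h))),
      frac_sites = if (n_sites_tot)
        length(unique(S4Vectors::queryHits(h))) / n_sites_tot else 0,
      n_intervals = length(in_cat),
      n_intervals_covered = length(unique(S4Vectors::subjectHits(h))),
      frac_intervals_covered =
        length(unique(S4Vectors::subjectHits(h))) / length(in_cat),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
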