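# Replicate and cross-sample statistics over SiteCounts tables.

# Per-site totals of detected sites (total >= 1), keyed "contig pos".
detected_totals <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("contig", "pos", "total") %in% names(counts)))
  d <- counts[counts$total >= 1L, , drop = FALSE]
  stats::setNames(d$total, paste(d$contig, d$pos))
}

#' Coverage distribution of detected sites
#'
#' Frequency distribution of per-site total read counts over sites with
#' at least one read, plus the fraction of detected sites below a count
#' threshold (the "fraction of sites covered by fewer than k tagged
#' reads" summary).
#'
#' @param counts A `SiteCounts` data.frame.
#' @return A `CoverageHistogram` list: `histogram` (data.frame `reads`,
#'   `n_sites`), `n_detected`, and `fraction_below(k)`.
#' @export
coverage_histogram <- function(counts) {
  tot <- detected_totals(counts)
  if (!length(tot)) stopf("no detected sites: empty coverage histogram")
  tab <- table(tot)
  hist <- data.frame(reads = as.integer(names(tab)),
                     n_sites = as.integer(tab))
  n <- length(tot)
  structure(
    list(histogram = hist, n_detected = n,
         fraction_below = function(k) sum(tot < k) / n),
    class = "CoverageHistogram"
  )
}

#' Pearson correlation between two libraries
#'
#' Correlates per-site total read counts over a site universe: the union
#' of detected sites (absent sites count 0) or their intersection. With
#' `min_count > 0`, sites where both libraries are below the cutoff are
#' excluded — raising the cutoff restricts the comparison to confidently
#' detected sites. `binary = TRUE` correlates presence/absence instead
#' of counts.
#'
#' @param a,b `SiteCounts` data.frames.
#' @param universe `"union"` or `"intersection"` of detected sites.
#' @param min_count Exclude sites with both totals below this.
#' @param binary Correlate detection indicators rather than counts.
#' @return Pearson's r, or `NA` (with a warning) when fewer than two
#'   universe sites remain or a side has zero variance.
#' @export
correlate_counts <- function(a, b, universe = c("union", "intersection"),
                             min_count = 0L, binary = FALSE) {
  universe <- match.arg(universe)
  ta <- detected_totals(a)
  tb <- detected_totals(b)
  keys <- if (universe == "union") union(names(ta), names(tb)) else
    intersect(names(ta), names(tb))
  va <- ifelse(keys %in% names(ta), ta[keys], 0L)
  vb <- ifelse(keys %in% names(tb), tb[keys], 0L)
  va[is.na(va)] <- 0L; vb[is.na(vb)] <- 0L
  if (min_count > 0L) {
    keep <- va >= min_count | vb >= min_count
    va <- va[keep]; vb <- vb[keep]
  }
  if (binary) { va <- as.integer(va >= 1L); vb <- as.integer(vb >= 1L) }
  if (length(va) < 2L || stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("Pearson correlation undefined: fewer than 2 sites or zero variance")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Site overlap between two libraries
#'
#' Venn-style comparison of the detected site sets at a count threshold,
#' together with the read-count distributions (quartiles) of shared
#' versus library-unique sites and the fraction of unique sites below a
#' count threshold — low counts at non-overlapping sites are the
#' signature of depth-limited detection of weak 5hmC.
#'
#' @param a,b `SiteCounts` data.frames.
#' @param min_count Detection threshold; sites count when
#'   `total >= max(1, min_count)`.
#' @param below Threshold for the `frac_unique_below` summaries.
#' @return A `ComparisonReport`-style list: `n_common`, `n_unique_a`,
#'   `n_unique_b`, `count_summary` (quartiles of totals for
#'   common/unique sites per library) and `frac_unique_below`.
#' @export
overlap_counts <- function(a, b, min_count = 1L, below = 3L) {
  thr <- max(1L, as.integer(min_count))
  ta <- detected_totals(a); ta <- ta[ta >= thr]
  tb <- detected_totals(b); tb <- tb[tb >= thr]
  common <- intersect(names(ta), names(tb))
  ua <- setdiff(names(ta), names(tb))
  ub <- setdiff(names(tb), names(ta))
  qs <- function(x) if (length(x)) stats::quantile(x, c(0, .25, .5, .75, 1)) else
    stats::setNames(rep(NA_real_, 5), c("0%", "25%", "50%", "75%", "100%"))
  uniq_counts <- c(ta[ua], tb[ub])
  list(
    n_common = length(common),
    n_unique_a = length(ua),
    n_unique_b = length(ub),
    count_summary = list(
      common_a = qs(ta[common]), common_b = qs(tb[common]),
      unique_a = qs(ta[ua]), unique_b = qs(tb[ub])
    ),
    frac_unique_below = if (length(uniq_counts))
      sum(uniq_counts < below) / length(uniq_counts) else NA_real_
  )
}

#' Strand asymmetry of 5hmC read counts
#'
#' Per-site log2 ratio of forward to reverse tagged-read counts
#' (pseudocount-stabilised), and a flag for sites whose raw counts differ
#' by at least `fold_threshold` between strands. The flag uses raw
#' counts: with one strand at zero, a site is flagged when the other
#' strand reaches `fold_threshold` reads.
#'
#' @param counts A `SiteCounts` data.frame (detected sites are used).
#' @param fold_threshold Fold difference for flagging (> 1).
#' @param pseudocount Added to both strands for the log ratio.
#' @return `data.frame`: `contig`, `pos`, `fwd_reads`, `rev_reads`,
#'   `log2_ratio`, `flagged`.
#' @export
strand_asymmetry <- function(counts, fold_threshold = 2, pseudocount = 1) {
  stopifnot(all(c("fwd_reads", "rev_reads") %in% names(counts)))
  if (fold_threshold <= 1) stopf("fold_threshold must be > 1")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  d <- counts[counts$total >= 1L, , drop = FALSE]
  f <- d$fwd_reads; r <- d$rev_reads
  mx <- pmax(f, r); mn <- pmin(f, r)
  data.frame(
    contig = d$contig, pos = d$pos, fwd_reads = f, rev_reads = r,
    log2_ratio = log2((f + pseudocount) / (r + pseudocount)),
    flagged = ifelse(mn == 0L, mx >= fold_threshold,
                     mx >= fold_threshold * mn),
    stringsAsFactors = FALSE
  )
}

#' Rank sites by paired read-count difference
#'
#' Differential display between paired libraries (e.g. tumor versus
#' adjacent normal): sites are ranked by absolute difference of total
#' read counts over the union of detected sites (absent = 0), ties
#' broken by genomic coordinate. No significance test is attached — the
#' ranking is by displayed 5hmC difference, and it assumes the two
#' libraries were sequenced to comparable depth (equal-volume
#' multiplexing); otherwise normalisation is the caller's problem.
#'
#' @param a,b `SiteCounts` data.frames.
#' @param top_n Number of top sites to return.
#' @return `data.frame`: `contig`, `pos`, `total_a`, `total_b`,
#'   `difference` (signed, a - b), strongest first.
#' @export
compare_paired <- function(a, b, top_n) {
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n <= 0L) stopf("top_n must be a positive integer")
  ta <- detected_totals(a)
  tb <- detected_totals(b)
  keys <- union(names(ta), names(tb))
  va <- ifelse(keys %in% names(ta), ta[keys], 0L); va[is.na(va)] <- 0L
  vb <- ifelse(keys %in% names(tb), tb[keys], 0L); vb[is.na(vb)] <- 0L
  parts <- strsplit(keys, " ", fixed = TRUE)
  d <- data.frame(
    contig = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    total_a = as.integer(va), total_b = as.integer(vb),
    difference = as.integer(va) - as.integer(vb),
    stringsAsFactors = FALSE
  )
  d <- d[order(-abs(d$difference), d$contig, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, top_n)
}
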