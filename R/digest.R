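#' Find restriction sites in a genome
#'
#' Scans every contig for forward-strand occurrences of the recognition
#' motif (default `CCGG`, the MspI/HpaII site). Overlapping occurrences
#' are each reported; occurrences containing `N` never match. Positions
#' are 0-based and refer to the first base of the motif (the first C of
#' CCGG).
#'
#' @param genome Genome (see [as_genome()]).
#' @param motif Recognition sequence; the default is the MspI site.
#' @return `data.frame` with columns `contig`, `pos` (0-based), sorted by
#'   `(contig, pos)` in genome contig order.
#' @examples
#' find_sites(c(chr = "ACCGGT"))
#' @export
find_sites <- function(genome, motif = "CCGG") {
  genome <- as_genome(genome)
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L ||
      grepl("[^ACGT]", toupper(motif))) {
    stopf("'motif' must be a single A/C/G/T string")
  }
  motif <- toupper(motif)
  subject <- Biostrings::DNAStringSet(genome)
  hits <- Biostrings::vmatchPattern(motif, subject, fixed = TRUE)
  n <- lengths(hits)
  pos <- unlist(lapply(hits, BiocGenerics::start), use.names = FALSE)
  out <- data.frame(
    contig = rep(names(genome), n),
    pos = if (length(pos)) as.integer(pos) - 1L else integer(0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' In silico digestion of a genome
#'
#' Cuts every contig at each forward-strand occurrence of the motif. For
#' the MspI pattern C^CGG the top-strand cut coordinate of a site at
#' 0-based position `pos` is `pos + cut_offset` (default `pos + 1`,
#' between the C and CGG). Fragments are the intervals between
#' consecutive cut coordinates plus the contig ends, so the fragments of
#' a contig tile it exactly; fragment length is the distance between
#' consecutive top-strand cuts (the 2-nt 5'-CG overhang is not
#' double-counted).
#'
#' @param genome Genome (see [as_genome()]).
#' @param motif Recognition sequence (default MspI `CCGG`).
#' @param cut_offset Top-strand cut position relative to the motif start.
#' @return A `FragmentCatalog`: list with `genome`, `fragments` (a
#'   `data.frame` with `contig`, `start`, `end` 0-based half-open,
#'   `length`, and `left_site`/`right_site` — the 0-based motif position
#'   whose cut formed that boundary, or `NA` at a contig end), `sites`
#'   (as [find_sites()]), `size_range` (`NULL` until [size_select()]),
#'   and `motif`.
#' @examples
#' cat <- digest_genome(c(chr = "TTCCGGAA"))
#' cat$fragments
#' @export
digest_genome <- function(genome, motif = "CCGG", cut_offset = 1L) {
  genome <- as_genome(genome)
  sites <- find_sites(genome, motif)
  frags <- lapply(names(genome), function(ctg) {
    len <- nchar(genome[[ctg]])
    spos <- sites$pos[sites$contig == ctg]
    cuts <- spos + as.integer(cut_offset)
    cuts <- cuts[cuts > 0L & cuts < len]   # cut at a boundary is a no-op
    spos <- spos[(spos + as.integer(cut_offset)) %in% cuts]
    start <- c(0L, cuts)
    end <- c(cuts, len)
    data.frame(
      contig = rep(ctg, length(start)),
      start = start,
      end = end,
      length = end - start,
      left_site = c(NA_integer_, spos),
      right_site = c(spos, NA_integer_),
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, frags)
  rownames(frags) <- NULL
  structure(
    list(genome = genome, fragments = frags, sites = sites,
         size_range = NULL, motif = motif, cut_offset = as.integer(cut_offset)),
    class = "FragmentCatalog"
  )
}

#' @export
print.FragmentCatalog <- function(x, ...) {
  cat(sprintf(
    "FragmentCatalog: %d contig(s), %d %s site(s), %d fragment(s)%s\n",
    length(x$genome), nrow(x$sites), x$motif, nrow(x$fragments),
    if (is.null(x$size_range)) "" else
      sprintf(", size-selected [%d, %d] bp", x$size_range[1], x$size_range[2])
  ))
  invisible(x)
}

#' Size-select fragments
#'
#' Retains fragments with length inside `[min_len, max_len]` inclusive,
#' emulating gel size selection in insert space. The default 40-430 bp
#' window corresponds to cutting an adapter-ligated library at 110-500 bp
#' with roughly 70 bp of adapter. After selection the fragments no longer
#' tile the contigs.
#'
#' @param catalog A `FragmentCatalog` from [digest_genome()].
#' @param min_len,max_len Inclusive insert-length bounds in bp.
#' @return The catalog with only in-range fragments and `size_range` set.
#' @export
size_select <- function(catalog, min_len = 40L, max_len = 430L) {
  stopifnot(inherits(catalog, "FragmentCatalog"))
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len < 1L || min_len > max_len) {
    stopf("size range must satisfy 1 <= min_len <= max_len")
  }
  keep <- catalog$fragments$length >= min_len & catalog$fragments$length <= max_len
  catalog$fragments <- catalog$fragments[keep, , drop = FALSE]
  rownames(catalog$fragments) <- NULL
  catalog$size_range <- c(min_len, max_len)
  catalog
}

#' Catalog of detectable junction sites
#'
#' A CCGG site is detectable on the forward strand if a retained fragment
#' begins at its cut (the read interrogates the forward-strand CpG
#' cytosine at `pos + 1`), and on the reverse strand if a retained
#' fragment ends at its cut (interrogating the reverse-strand cytosine at
#' `pos + 2`). Sites bordering only a contig end are not detectable from
#' that side: contig ends carry no adapter junction.
#'
#' @param catalog A `FragmentCatalog`, normally after [size_select()].
#' @return A `SiteCatalog`: `data.frame` with `contig`, `pos`,
#'   `fwd_detectable`, `rev_detectable`, sorted by `(contig, pos)`; every
#'   row has at least one flag `TRUE`.
#' @export
detectable_sites <- function(catalog) {
  stopifnot(inherits(catalog, "FragmentCatalog"))
  fr <- catalog$fragments
  empty <- data.frame(contig = character(0), pos = integer(0),
                      fwd_detectable = logical(0), rev_detectable = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(fr) == 0L) return(structure(empty, class = c("SiteCatalog", "data.frame")))
  fwd <- fr[!is.na(fr$left_site), c("contig", "left_site")]
  rev <- fr[!is.na(fr$right_site), c("contig", "right_site")]
  names(fwd)[2] <- "pos"; names(rev)[2] <- "pos"
  key <- function(d) paste(d$contig, d$pos)
  all <- unique(rbind(fwd, rev))
  all$fwd_detectable <- key(all) %in% key(fwd)
  all$rev_detectable <- key(all) %in% key(rev)
  ord <- order(match(all$contig, names(catalog$genome)), all$pos)
  all <- all[ord, , drop = FALSE]
  rownames(all) <- NULL
  structure(all, class = c("SiteCatalog", "data.frame"))
}
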