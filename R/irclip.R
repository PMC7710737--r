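#' Infer crosslink sites from irCLIP alignments
#'
#' Reverse transcription stops one nucleotide 3' of the crosslinked base, so
#' the crosslink site is taken 1 nt upstream (5') of each mapped read start.
#' Reads starting at transcript position 1 have no upstream base and are
#' dropped (counted); reads antisense to the transcript are discarded
#' (counted) since the transcript is expressed sense-only.
#'
#' @param alignments `data.frame` with `start`, `end` (1-based closed) and
#'   optionally `strand` (`"+"`/`"-"`, default all `"+"`).
#' @param transcriptLength transcript length for bounds checking.
#' @param dedup collapse alignments with identical start and end before site
#'   calling (default `FALSE`), an exact-duplicate stand-down for PCR
#'   duplicates.
#' @return `data.frame` with `pos` (1-based site) and `count`, sorted by
#'   position, with attributes `n_dropped_edge` (reads at position 1) and
#'   `n_antisense`.
#' @examples
#' crosslinkSites(data.frame(start = c(101, 101, 101), end = 135))
#' @export
crosslinkSites <- function(alignments, transcriptLength = NULL,
                           dedup = FALSE) {
  st <- alignments$start
  en <- alignments$end
  checkInterval(st, en, "alignment")
  strand <- if ("strand" %in% names(alignments)) alignments$strand
            else rep("+", length(st))
  anti <- strand == "-"
  st <- st[!anti]; en <- en[!anti]
  if (dedup) {
    keep <- !duplicated(paste(st, en))
    st <- st[keep]; en <- en[keep]
  }
  if (!is.null(transcriptLength) && length(st) &&
      (any(st < 1L) || any(en > transcriptLength)))
    stop("alignment outside transcript bounds [1, ", transcriptLength, "]")
  site <- st - 1L
  edge <- site < 1L
  site <- site[!edge]
  tab <- table(site)
  out <- data.frame(pos = as.integer(names(tab)),
                    count = as.integer(tab))
  attr(out, "n_dropped_edge") <- sum(edge)
  attr(out, "n_antisense") <- sum(anti)
  out
}

#' Call replicate-supported crosslink clusters
#'
#' The shift/extend/intersect/trim procedure: each replicate's crosslink
#' sites are extended `extend` nt upstream and downstream into closed local
#' intervals (overlapping intervals within a replicate merged); only
#' intervals overlapping between the two replicates are kept; each
#' cross-replicate intersection is then trimmed `trim` nt from each side to
#' shape the final cluster, and intersections narrower than `2 * trim + 1`
#' vanish. With the defaults (5/5) two isolated single sites yield a cluster
#' only where they coincide exactly.
#'
#' @param rep1,rep2 site tables from [crosslinkSites()] (columns `pos`,
#'   `count`).
#' @param extend nt added each side of a site (default 5).
#' @param trim nt removed from each side of an intersection (default 5).
#' @return `data.frame` with `start`, `end` (1-based closed cluster
#'   interval), `sites_rep1`, `sites_rep2` (supporting raw sites within
#'   `extend` nt of the cluster) and `reads_rep1`, `reads_rep2` (their read
#'   counts). Zero rows when either replicate is empty (with a warning).
#' @examples
#' r1 <- data.frame(pos = 100, count = 5)
#' r2 <- data.frame(pos = 100, count = 3)
#' callClusters(r1, r2)  # single 1-nt cluster at 100
#' @importFrom IRanges reduce
#' @export
callClusters <- function(rep1, rep2, extend = 5, trim = 5) {
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) {
    warning("a replicate has zero crosslink sites; no clusters called")
    return(data.frame(start = integer(), end = integer(),
                      sites_rep1 = integer(), sites_rep2 = integer(),
                      reads_rep1 = integer(), reads_rep2 = integer()))
  }
  ext <- function(sites)
    IRanges::reduce(IRanges(sites$pos - extend, sites$pos + extend))
  i1 <- ext(rep1); i2 <- ext(rep2)
  inter <- IRanges::intersect(i1, i2)
  ts <- start(inter) + trim
  te <- end(inter) - trim
  keep <- te >= ts
  ts <- ts[keep]; te <- te[keep]
  nearIdx <- function(sites, s, e)
    lapply(seq_along(s), function(i)
      which(sites$pos >= s[i] - extend & sites$pos <= e[i] + extend))
  id1 <- nearIdx(rep1, ts, te)
  id2 <- nearIdx(rep2, ts, te)
  data.frame(start = ts, end = te,
             sites_rep1 = lengths(id1), sites_rep2 = lengths(id2),
             reads_rep1 = vapply(id1, function(i) sum(rep1$count[i]), numeric(1)),
             reads_rep2 = vapply(id2, function(i) sum(rep2$count[i]), numeric(1)))
}

#' Write crosslink sites as bedGraph and clusters as BED
#'
#' Sites become single-nt bedGraph intervals scored by read count; clusters
#' become BED records scored by total supporting reads, converted to BED's
#' 0-based half-open convention.
#'
#' @param sites site table from [crosslinkSites()].
#' @param file output path.
#' @param transcriptName chrom field.
#' @export
writeSiteTrack <- function(sites, file, transcriptName = "transcript") {
  gr <- GenomicRanges::GRanges(transcriptName,
                               IRanges(sites$pos, width = 1L),
                               score = sites$count)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname writeSiteTrack
#' @param clusters cluster table from [callClusters()].
#' @export
writeClusterBed <- function(clusters, file, transcriptName = "transcript") {
  gr <- GenomicRanges::GRanges(transcriptName,
                               IRanges(clusters$start, clusters$end))
  gr$name <- sprintf("cluster_%d:%d/%d", seq_len(nrow(clusters)),
                     clusters$sites_rep1, clusters$sites_rep2)
  gr$score <- clusters$reads_rep1 + clusters$reads_rep2
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
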