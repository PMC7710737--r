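#' Classify paired-end tag pairs as short (single fragment) or long (chimera)
#'
#' In lightly crosslinked RIP libraries most read pairs come from one RNA
#' fragment, so the two 31-nt sequence tags sit within a few hundred nt of
#' each other. A minority of pairs span kilobases: these arise from two
#' proximally ligated fragments and are the raw evidence for long-range
#' spatial contacts. The pair span is the inclusive outer distance
#' `max(tag ends) - min(tag starts) + 1` (1-based closed coordinates); a pair
#' is `long` iff its span strictly exceeds `longThreshold`.
#'
#' @param pairs `data.frame` with columns `start1`, `end1`, `start2`, `end2`
#'   (1-based closed, both tags on the same transcript) and optionally
#'   `read_id`, `sample_id`.
#' @param longThreshold span cutoff in nt; sonicated fragments are mostly
#'   100-400 nt, so the default 1000 leaves margin against the fragment-size
#'   tail.
#' @param transcriptLength if given, tags are validated against
#'   `[1, transcriptLength]`.
#' @return `pairs` with added columns `span` (nt) and `class`
#'   (`"short"`/`"long"`).
#' @examples
#' p <- data.frame(start1 = 101, end1 = 131, start2 = 9001, end2 = 9031)
#' classifyPairs(p)$class  # "long"
#' @export
classifyPairs <- function(pairs, longThreshold = 1000,
                          transcriptLength = NULL) {
  validatePairs(pairs, transcriptLength)
  pairs$span <- pmax(pairs$end1, pairs$end2) -
    pmin(pairs$start1, pairs$start2) + 1L
  pairs$class <- ifelse(pairs$span > longThreshold, "long", "short")
  pairs
}

validatePairs <- function(pairs, transcriptLength = NULL) {
  need <- c("start1", "end1", "start2", "end2")
  if (!all(need %in% names(pairs)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  checkInterval(pairs$start1, pairs$end1, "tag1")
  checkInterval(pairs$start2, pairs$end2, "tag2")
  if (!is.null(transcriptLength)) {
    if (any(pairs$start1 < 1L | pairs$start2 < 1L |
            pairs$end1 > transcriptLength | pairs$end2 > transcriptLength))
      stop("tag outside transcript bounds [1, ", transcriptLength, "]")
  }
  invisible(TRUE)
}

#' Fraction of long-distance read pairs in a sample
#'
#' The per-protein chimeric yield: long pairs over all mapped pairs. Proteins
#' whose binding sites sit at the junctions of folded domains pull down more
#' proximity-ligated chimeras, so this fraction tracks involvement in
#' long-range architecture.
#'
#' @inheritParams classifyPairs
#' @return a single fraction in `[0, 1]`.
#' @export
longPairFraction <- function(pairs, longThreshold = 1000) {
  if (nrow(pairs) == 0L)
    stop("no mapped pairs: long-pair fraction is undefined")
  cl <- classifyPairs(pairs, longThreshold)
  mean(cl$class == "long")
}

#' Collapse duplicate read pairs
#'
#' Pairs with identical tag coordinates on both sides are collapsed to one,
#' as PCR duplicates would otherwise inflate long-group support.
#'
#' @inheritParams classifyPairs
#' @return the deduplicated pair table.
#' @export
dedupPairs <- function(pairs) {
  key <- paste(pairs$start1, pairs$end1, pairs$start2, pairs$end2)
  pairs[!duplicated(key), , drop = FALSE]
}

#' Call long-distance groups (LGs) from long pairs
#'
#' Each long pair is a point in the 2-D space of (5' tag midpoint, 3' tag
#' midpoint); discrete clusters in this space are ligation anchor pairs.
#' Pairs are grouped by single-linkage clustering under the Chebyshev
#' (maximum-coordinate) metric at `linkDistance`, i.e. two pairs join a
#' group when both their 5' and their 3' midpoints are within
#' `linkDistance` nt. Groups supported by fewer than `minSupport`
#' (deduplicated) pairs are discarded. Anchors are the bounding intervals of
#' the member tags on each side.
#'
#' @param pairs long pairs (`data.frame` as in [classifyPairs()]; rows with a
#'   `class` column are filtered to `"long"`).
#' @param linkDistance single-linkage merge radius in nt (default 500).
#' @param minSupport minimum deduplicated pairs per group (default 5).
#' @param dedup collapse identical pairs before support counting
#'   (default `TRUE`).
#' @return `data.frame` with one row per LG: `lg_id`, `left_start`,
#'   `left_end`, `right_start`, `right_end`, `support`, and a list-column
#'   `members` of row indices into the (deduplicated, oriented) input.
#' @examples
#' p <- data.frame(start1 = c(1000, 1050, 1080), end1 = c(1030, 1080, 1110),
#'                 start2 = c(8000, 8010, 8100), end2 = c(8030, 8040, 8130))
#' callLongGroups(p, linkDistance = 500, minSupport = 3)
#' @importFrom igraph components make_empty_graph add_edges
#' @export
callLongGroups <- function(pairs, linkDistance = 500, minSupport = 5,
                           dedup = TRUE) {
  if (nrow(pairs) == 0L) return(emptyLgTable())
  validatePairs(pairs)
  if ("class" %in% names(pairs)) pairs <- pairs[pairs$class == "long", ]
  if (dedup) pairs <- dedupPairs(pairs)
  n <- nrow(pairs)
  if (n == 0L) return(emptyLgTable())
  # orient each pair so tag "left" is the 5' one
  m1 <- (pairs$start1 + pairs$end1) / 2
  m2 <- (pairs$start2 + pairs$end2) / 2
  swap <- m1 > m2
  ls <- ifelse(swap, pairs$start2, pairs$start1)
  le <- ifelse(swap, pairs$end2, pairs$end1)
  rs <- ifelse(swap, pairs$start1, pairs$start2)
  re <- ifelse(swap, pairs$end1, pairs$end2)
  ml <- (ls + le) / 2; mr <- (rs + re) / 2
  # connected components of the "Chebyshev distance <= linkDistance" graph
  # == single-linkage clusters cut at linkDistance
  if (n == 1L) {
    comp <- 1L
  } else {
    d <- pmax(abs(outer(ml, ml, "-")), abs(outer(mr, mr, "-")))
    adj <- which(d <= linkDistance & upper.tri(d), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
    comp <- igraph::components(g)$membership
  }
  groups <- split(seq_len(n), comp)
  groups <- groups[lengths(groups) >= minSupport]
  if (!length(groups)) return(emptyLgTable())
  # order groups by left anchor position for stable ids
  lstart <- vapply(groups, function(i) min(ls[i]), numeric(1))
  groups <- groups[order(lstart)]
  out <- data.frame(
    lg_id = sprintf("LG%d", seq_along(groups)),
    left_start = vapply(groups, function(i) as.integer(min(ls[i])), 1L),
    left_end = vapply(groups, function(i) as.integer(max(le[i])), 1L),
    right_start = vapply(groups, function(i) as.integer(min(rs[i])), 1L),
    right_end = vapply(groups, function(i) as.integer(max(re[i])), 1L),
    support = lengths(groups)
  )
  rownames(out) <- NULL
  out$members <- unname(groups)
  out
}

emptyLgTable <- function() {
  out <- data.frame(lg_id = character(), left_start = integer(),
                    left_end = integer(), right_start = integer(),
                    right_end = integer(), support = integer())
  out$members <- list()
  out
}

#' Extend sequence tags to the estimated fragment length
#'
#' Sequenced tags cover only the ends of each RNA fragment; for footprint
#' comparisons (for example against duplex-group arms) each tag is extended
#' to the average fragment size: tag1 downstream and tag2 upstream, clipped
#' to the transcript. Tags already wider than `fragmentLen` are returned
#' unchanged with a warning.
#'
#' @inheritParams classifyPairs
#' @param fragmentLen target width in nt (default 194, the average
#'   RIP fragment size).
#' @param transcriptLength transcript length for clipping.
#' @return `pairs` with tag coordinates replaced by the extended ones.
#' @export
extendToFragment <- function(pairs, fragmentLen = 194,
                             transcriptLength = NULL) {
  validatePairs(pairs, transcriptLength)
  w1 <- pairs$end1 - pairs$start1 + 1L
  w2 <- pairs$end2 - pairs$start2 + 1L
  if (any(w1 > fragmentLen) || any(w2 > fragmentLen))
    warning("some tags are wider than fragmentLen; returned unchanged")
  pairs$end1 <- ifelse(w1 > fragmentLen, pairs$end1,
                       pairs$start1 + fragmentLen - 1L)
  pairs$start2 <- ifelse(w2 > fragmentLen, pairs$start2,
                         pairs$end2 - fragmentLen + 1L)
  if (!is.null(transcriptLength))
    pairs$end1 <- pmin(pairs$end1, transcriptLength)
  pairs$start2 <- pmax(pairs$start2, 1L)
  pairs
}

#' Match long-distance groups against duplex groups
#'
#' An LG supports a duplex group (DG) when its fragment-extended anchors
#' cover both duplex arms: the extended left anchor must intersect one arm
#' and the extended right anchor the other, in either arm order. This links
#' ligation-derived contacts to base-paired duplexes mapped independently.
#'
#' @param lgs LG table from [callLongGroups()].
#' @param dgs duplex-group `data.frame` (`id`, `l_start`, `l_end`, `r_start`,
#'   `r_end`, 1-based closed).
#' @param extension nt added on both sides of each LG anchor before
#'   intersection (default 194, the fragment-size extension).
#' @return `data.frame` with one row per LG: `lg_id`, `n_matched`, and a
#'   comma-separated `dg_ids` of matched duplex groups.
#' @export
lgDgOverlap <- function(lgs, dgs, extension = 194) {
  out <- data.frame(lg_id = lgs$lg_id, n_matched = 0L,
                    dg_ids = "", stringsAsFactors = FALSE)
  if (nrow(lgs) == 0L || nrow(dgs) == 0L) return(out)
  for (i in seq_len(nrow(lgs))) {
    ls <- lgs$left_start[i] - extension; le <- lgs$left_end[i] + extension
    rs <- lgs$right_start[i] - extension; re <- lgs$right_end[i] + extension
    direct <- intervalsOverlap(ls, le, dgs$l_start, dgs$l_end) &
      intervalsOverlap(rs, re, dgs$r_start, dgs$r_end)
    swapped <- intervalsOverlap(ls, le, dgs$r_start, dgs$r_end) &
      intervalsOverlap(rs, re, dgs$l_start, dgs$l_end)
    hit <- direct | swapped
    out$n_matched[i] <- sum(hit)
    out$dg_ids[i] <- paste(dgs$id[hit], collapse = ",")
  }
  out
}

#' Read / write paired-end tag tables
#'
#' The on-disk pair table is tab-delimited with header columns `read_id`,
#' `start1`, `end1`, `start2`, `end2` in 0-based half-open coordinates
#' (BED-like); in memory coordinates are 1-based closed.
#'
#' @param file path to the TSV.
#' @return [readPairTable()] returns the pair `data.frame`.
#' @export
readPairTable <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("read_id", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(tab)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  tab$start1 <- tab$start1 + 1L
  tab$start2 <- tab$start2 + 1L
  tab
}

#' @rdname readPairTable
#' @param pairs in-memory pair table (1-based closed).
#' @export
writePairTable <- function(pairs, file) {
  out <- pairs[, intersect(c("read_id", "start1", "end1", "start2", "end2",
                             "span", "class"), names(pairs))]
  out$start1 <- out$start1 - 1L
  out$start2 <- out$start2 - 1L
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Per-nucleotide tag coverage from a pair table
#'
#' Sums the per-base coverage of both sequence tags of each pair (not the
#' unsequenced fragment interior), e.g. for the all-tag and long-tag
#' coverage tracks.
#'
#' @inheritParams classifyPairs
#' @param transcriptLength length of the coverage vector.
#' @return numeric vector of length `transcriptLength`.
#' @importFrom IRanges coverage
#' @export
pairTagCoverage <- function(pairs, transcriptLength) {
  validatePairs(pairs, transcriptLength)
  ir <- IRanges(start = c(pairs$start1, pairs$start2),
                end = c(pairs$end1, pairs$end2))
  as.numeric(IRanges::coverage(ir, width = transcriptLength))
}
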