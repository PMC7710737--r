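#' Build the mature transcript sequence from exon blocks
#'
#' Concatenates the exon intervals of a [TranscriptModel-class] out of the
#' genomic sequence; minus-strand models are reverse-complemented so the
#' result reads 5' to 3' on the mature RNA. This is the "mini-genome"
#' sequence that all transcript-space analyses align against.
#'
#' @param model a [TranscriptModel-class].
#' @param genomeSeq genomic sequence covering all exons: a
#'   [Biostrings::DNAString] or a plain character string.
#' @return a [Biostrings::DNAString] of length `transcriptLength(model)`.
#' @examples
#' m <- TranscriptModel("tx", IRanges::IRanges(c(1, 11), c(5, 15)))
#' buildTranscriptSeq(m, "AAAAACCCCCGGGGG")  # AAAAAGGGGG
#' @importFrom Biostrings DNAString reverseComplement subseq
#' @importFrom Biostrings xscat
#' @export
buildTranscriptSeq <- function(model, genomeSeq) {
  stopifnot(is(model, "TranscriptModel"))
  if (is.character(genomeSeq)) genomeSeq <- DNAString(genomeSeq)
  ex <- exonBlocks(model)
  if (max(end(ex)) > length(genomeSeq))
    stop(sprintf("exon interval [%d, %d] outside genome sequence (length %d)",
                 start(ex)[which.max(end(ex))], max(end(ex)),
                 length(genomeSeq)))
  pieces <- lapply(seq_along(ex), function(i)
    subseq(genomeSeq, start(ex)[i], end(ex)[i]))
  seq <- do.call(xscat, pieces)
  if (model@strand == "-") seq <- reverseComplement(seq)
  seq
}

# Cumulative transcript offset preceding each exon (plus-strand orientation).
exonOffsets <- function(model) {
  w <- width(exonBlocks(model))
  cumsum(c(0L, w[-length(w)]))
}

#' Lift genomic intervals onto the mature transcript
#'
#' Maps each genomic interval through the exon blocks of a transcript model.
#' The exonic portions are concatenated in transcript order; the reported
#' interval is the bounding span of the mapped bases, with the number of
#' mapped bases and the mapped fraction so that partial (intron-spanning)
#' lifts can be filtered. Intervals touching no exon are returned unmapped
#' (`NA` coordinates, fraction 0).
#'
#' @param intervals an [IRanges::IRanges] of genomic query intervals
#'   (1-based closed).
#' @param model a [TranscriptModel-class].
#' @return a `data.frame` with one row per query: `start`, `end` (transcript
#'   coordinates or `NA`), `mapped_bases`, `mapped_fraction`.
#' @examples
#' m <- TranscriptModel("tx", IRanges::IRanges(c(101, 301), c(200, 400)))
#' liftGenomeToTranscript(IRanges::IRanges(151, 160), m)  # 51..60
#' @export
liftGenomeToTranscript <- function(intervals, model) {
  stopifnot(is(model, "TranscriptModel"), is(intervals, "IRanges"))
  if (any(width(intervals) < 1L))
    stop("malformed interval: width < 1")
  ex <- exonBlocks(model)
  off <- exonOffsets(model)
  L <- transcriptLength(model)
  nq <- length(intervals)
  out <- data.frame(start = rep(NA_integer_, nq),
                    end = rep(NA_integer_, nq),
                    mapped_bases = rep(0L, nq),
                    mapped_fraction = rep(0, nq))
  for (q in seq_along(intervals)) {
    qs <- start(intervals)[q]; qe <- end(intervals)[q]
    ts <- integer(); te <- integer()
    for (i in seq_along(ex)) {
      os <- max(qs, start(ex)[i]); oe <- min(qe, end(ex)[i])
      if (os > oe) next
      ts <- c(ts, off[i] + (os - start(ex)[i]) + 1L)
      te <- c(te, off[i] + (oe - start(ex)[i]) + 1L)
    }
    if (!length(ts)) next
    if (model@strand == "-") {
      flip_s <- L - te + 1L; flip_e <- L - ts + 1L
      ts <- flip_s; te <- flip_e
    }
    out$start[q] <- min(ts); out$end[q] <- max(te)
    out$mapped_bases[q] <- sum(te - ts + 1L)
    out$mapped_fraction[q] <- out$mapped_bases[q] / width(intervals)[q]
  }
  out
}

#' Lift transcript intervals back to genomic sub-intervals
#'
#' The inverse of [liftGenomeToTranscript()]: a transcript interval is mapped
#' back to the genomic sub-intervals (one per exon it crosses).
#'
#' @param intervals an [IRanges::IRanges] in transcript coordinates.
#' @param model a [TranscriptModel-class].
#' @return a list of [IRanges::IRanges], one per query, each holding the
#'   genomic sub-intervals in genomic order.
#' @export
liftTranscriptToGenome <- function(intervals, model) {
  stopifnot(is(model, "TranscriptModel"), is(intervals, "IRanges"))
  L <- transcriptLength(model)
  if (any(start(intervals) < 1L) || any(end(intervals) > L))
    stop("transcript interval outside [1, transcript length]")
  ex <- exonBlocks(model)
  off <- exonOffsets(model)
  lapply(seq_along(intervals), function(q) {
    qs <- start(intervals)[q]; qe <- end(intervals)[q]
    if (model@strand == "-") {
      tmp <- qs; qs <- L - qe + 1L; qe <- L - tmp + 1L
    }
    gs <- integer(); ge <- integer()
    for (i in seq_along(ex)) {
      # transcript footprint of exon i (plus-strand orientation)
      es <- off[i] + 1L; ee <- off[i] + width(ex)[i]
      os <- max(qs, es); oe <- min(qe, ee)
      if (os > oe) next
      gs <- c(gs, start(ex)[i] + (os - es))
      ge <- c(ge, start(ex)[i] + (oe - es))
    }
    IRanges(start = gs, end = ge)
  })
}

#' Lift transcript intervals through an alignment chain
#'
#' Maps each base of a query interval through its containing chain block;
#' bases falling in chain gaps are dropped. The result is the bounding span
#' of the mapped bases on the target transcript, with the mapped fraction
#' for filtering partial lifts (an interval with zero mapped bases is
#' unmapped).
#'
#' @param intervals an [IRanges::IRanges] in source-transcript coordinates.
#' @param chain a [LiftChain-class].
#' @param minFraction lifts with `mapped_fraction` below this are set to
#'   unmapped (default 0 keeps all partial lifts; 0.5 is a common filter).
#' @return a `data.frame` with `start`, `end` (target coordinates or `NA`),
#'   `mapped_bases`, `mapped_fraction`.
#' @examples
#' ch <- LiftChain(IRanges::IRanges(1, 100), IRanges::IRanges(201, 300))
#' liftViaChain(IRanges::IRanges(11, 20), ch)  # 211..220
#' @export
liftViaChain <- function(intervals, chain, minFraction = 0) {
  stopifnot(is(chain, "LiftChain"), is(intervals, "IRanges"))
  src <- chain@source; tgt <- chain@target
  nq <- length(intervals)
  out <- data.frame(start = rep(NA_integer_, nq),
                    end = rep(NA_integer_, nq),
                    mapped_bases = rep(0L, nq),
                    mapped_fraction = rep(0, nq))
  for (q in seq_along(intervals)) {
    qs <- start(intervals)[q]; qe <- end(intervals)[q]
    ts <- integer(); te <- integer()
    for (i in seq_along(src)) {
      os <- max(qs, start(src)[i]); oe <- min(qe, end(src)[i])
      if (os > oe) next
      shift <- start(tgt)[i] - start(src)[i]
      ts <- c(ts, os + shift); te <- c(te, oe + shift)
    }
    if (!length(ts)) next
    mb <- sum(te - ts + 1L)
    frac <- mb / width(intervals)[q]
    if (frac < minFraction) next
    out$start[q] <- min(ts); out$end[q] <- max(te)
    out$mapped_bases[q] <- mb
    out$mapped_fraction[q] <- frac
  }
  out
}

#' Lift a duplex-group table between transcripts
#'
#' Lifts both arms of each duplex group through a chain, keeping groups for
#' which both arms lift with at least `minFraction` of their bases mapped.
#' Arms are re-sorted so the left arm stays 5' of the right arm.
#'
#' @param dgs a duplex-group `data.frame` (see [readDgTable()]).
#' @param chain a [LiftChain-class].
#' @param minFraction minimum mapped-base fraction per arm (default 0.5).
#' @return the lifted duplex-group `data.frame` (possibly fewer rows).
#' @export
liftDgTable <- function(dgs, chain, minFraction = 0.5) {
  l <- liftViaChain(IRanges(dgs$l_start, dgs$l_end), chain, minFraction)
  r <- liftViaChain(IRanges(dgs$r_start, dgs$r_end), chain, minFraction)
  keep <- !is.na(l$start) & !is.na(r$start)
  out <- dgs[keep, , drop = FALSE]
  # re-orient so that the left arm stays 5'
  swap <- l$start[keep] > r$start[keep]
  out$l_start <- ifelse(swap, r$start[keep], l$start[keep])
  out$l_end   <- ifelse(swap, r$end[keep],   l$end[keep])
  out$r_start <- ifelse(swap, l$start[keep], r$start[keep])
  out$r_end   <- ifelse(swap, l$end[keep],   r$end[keep])
  rownames(out) <- NULL
  out
}

#' Read / write a lift chain as a block table
#'
#' The on-disk chain is a 4-column tab-delimited table
#' (`src_start`, `src_end`, `tgt_start`, `tgt_end`) in 0-based half-open
#' coordinates, one aligned block per line.
#'
#' @param file path to the chain TSV.
#' @param sourceName,targetName coordinate-system labels.
#' @return [readChain()] returns a [LiftChain-class]; [writeChain()] returns
#'   `file` invisibly.
#' @export
readChain <- function(file, sourceName = "source", targetName = "target") {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  need <- c("src_start", "src_end", "tgt_start", "tgt_end")
  if (!all(need %in% names(tab)))
    stop("chain table must have columns: ", paste(need, collapse = ", "))
  LiftChain(IRanges(tab$src_start + 1L, tab$src_end),
            IRanges(tab$tgt_start + 1L, tab$tgt_end),
            sourceName, targetName)
}

#' @rdname readChain
#' @param chain a [LiftChain-class] to write.
#' @export
writeChain <- function(chain, file) {
  tab <- data.frame(src_start = start(chain@source) - 1L,
                    src_end = end(chain@source),
                    tgt_start = start(chain@target) - 1L,
                    tgt_end = end(chain@target))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write transcript annotations as BED
#'
#' BED records (0-based half-open on disk) are converted to named 1-based
#' [IRanges::IRanges]. The BED name field carries the annotation name
#' (repeat unit or domain); the chrom field is the transcript name.
#'
#' @param file BED file path.
#' @return [readBedAnnotations()] returns a named [IRanges::IRanges].
#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges ranges
#' @export
readBedAnnotations <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  ir <- GenomicRanges::ranges(gr)
  nm <- if (!is.null(gr$name)) gr$name else rep("", length(gr))
  names(ir) <- nm
  ir
}

#' @rdname readBedAnnotations
#' @param intervals named [IRanges::IRanges] in transcript coordinates.
#' @param transcriptName chrom field value.
#' @importFrom GenomicRanges GRanges
#' @export
writeBedAnnotations <- function(intervals, file, transcriptName = "transcript") {
  gr <- GenomicRanges::GRanges(transcriptName, intervals)
  gr$name <- if (!is.null(names(intervals))) names(intervals)
             else as.character(seq_along(intervals))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
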