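#' Read alignments from SAM/BAM into tabular form
#'
#' Convenience readers for alignments against a mini-genome reference.
#' `readAlignmentsSam()` returns single-end alignments (`start`, `end`,
#' `strand`) for crosslink-site calling; `readPairsSam()` pairs mates by
#' read name and returns the 5-column pair table used by the chimera
#' module. A `.sam` file is converted to BAM on the fly.
#'
#' Alignment end positions are computed from the CIGAR reference width, so
#' indel-containing alignments keep their genomic footprint.
#'
#' @param file path to a SAM or BAM file.
#' @return `readAlignmentsSam()`: `data.frame` with `start`, `end`,
#'   `strand`; `readPairsSam()`: `data.frame` with `read_id`, `start1`,
#'   `end1`, `start2`, `end2` (1-based closed).
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
#' @export
readAlignmentsSam <- function(file) {
  bam <- ensureBam(file)
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(
      what = c("pos", "cigar", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  data.frame(start = res$pos, end = res$pos + w - 1L,
             strand = as.character(res$strand))
}

#' @rdname readAlignmentsSam
#' @export
readPairsSam <- function(file) {
  bam <- ensureBam(file)
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "pos", "cigar", "flag"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isPaired = TRUE)))[[1]]
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  first <- bitwAnd(res$flag, 64L) > 0L
  d1 <- data.frame(read_id = res$qname[first], start1 = res$pos[first],
                   end1 = res$pos[first] + w[first] - 1L)
  d2 <- data.frame(read_id = res$qname[!first], start2 = res$pos[!first],
                   end2 = res$pos[!first] + w[!first] - 1L)
  out <- merge(d1, d2, by = "read_id")
  out[order(out$start1, out$start2), , drop = FALSE]
}

ensureBam <- function(file) {
  if (grepl("\\.bam$", file, ignore.case = TRUE)) return(file)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(file, dest, overwrite = TRUE, indexDestination = FALSE)
}
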