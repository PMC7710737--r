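#' Average per-nucleotide signal over tandem repeat units
#'
#' Position-wise arithmetic mean of a signal track across the (equal-width)
#' units of a tandem repeat, with optional flanking spacer on each side.
#' Units whose flanked footprint extends outside the transcript are dropped
#' with a warning. Averaging over units reveals intra-unit structure -- for
#' example crosslinking concentrated in single-stranded spacers between
#' base-paired repeat cores.
#'
#' @param signal numeric per-nt vector in transcript coordinates.
#' @param units [IRanges::IRanges] of equal-width repeat-unit intervals.
#' @param flank nt of flanking sequence added on each side (default 0).
#' @return list of class `RepeatAverageProfile`: `profile` (length
#'   `unit width + 2 * flank`), `offset` (position of each profile entry
#'   relative to unit start, starting at `-flank`), `n_units`, `unit_width`,
#'   `flank`.
#' @examples
#' sig <- rep(0, 40); sig[c(13, 23)] <- 5
#' averageOverUnits(sig, IRanges::IRanges(c(11, 21), width = 4))$profile
#' @export
averageOverUnits <- function(signal, units, flank = 0) {
  if (length(units) == 0L) stop("no repeat units supplied")
  w <- unique(width(units))
  if (length(w) != 1L) stop("repeat units must have equal width")
  L <- length(signal)
  ok <- start(units) - flank >= 1L & end(units) + flank <= L
  if (!all(ok)) {
    warning(sum(!ok), " unit(s) extend outside the transcript with flank ",
            flank, "; dropped")
    units <- units[ok]
  }
  if (length(units) == 0L) stop("no repeat units remain after clipping")
  rows <- vapply(seq_along(units), function(i) {
    s <- start(units)[i] - flank
    signal[s:(s + w + 2L * flank - 1L)]
  }, numeric(w + 2L * flank))
  prof <- rowMeans(rows)
  structure(list(profile = prof,
                 offset = seq(-flank, w + flank - 1L),
                 n_units = length(units), unit_width = w, flank = flank),
            class = "RepeatAverageProfile")
}

#' @export
print.RepeatAverageProfile <- function(x, ...) {
  cat(sprintf(
    "RepeatAverageProfile: %d-nt unit + %d-nt flanks, averaged over %d units\n",
    x$unit_width, x$flank, x$n_units))
  invisible(x)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Scan a transcript sequence for a degenerate IUPAC motif
#'
#' Returns every (overlapping) start position at which each motif position's
#' IUPAC code set contains the sequence base. T and U are equivalent. The
#' matching itself is done by [Biostrings::matchPattern()] with
#' `fixed = "subject"`, which implements exactly this containment semantics
#' for unambiguous subjects.
#'
#' @param sequence transcript sequence ([Biostrings::DNAString] or character;
#'   U is converted to T).
#' @param motif IUPAC motif string, e.g. `"DRACH"` for the m6A consensus.
#' @return integer vector of 1-based match start positions.
#' @examples
#' scanMotif("GGACT", "DRACH")  # 1
#' scanMotif("CCCCC", "CCCC")   # 1 2
#' @importFrom Biostrings matchPattern
#' @export
scanMotif <- function(sequence, motif) {
  motif <- chartr("u", "U", toupper(motif))
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ", "))
  motif <- chartr("U", "T", motif)
  if (is.character(sequence))
    sequence <- DNAString(chartr("Uu", "Tt", toupper(sequence)))
  hits <- Biostrings::matchPattern(motif, sequence, fixed = "subject")
  start(hits)
}

#' Motif density in sliding windows
#'
#' Counts motif-match starts per window of width `window`, sliding by
#' `step`, divided by the window width; the last partial window is divided
#' by its actual width so terminal density is not artificially depressed.
#'
#' @param positions integer match starts (1-based), e.g. from [scanMotif()].
#' @param transcriptLength transcript length in nt.
#' @param window window width in nt (default 300).
#' @param step step between window starts in nt (default 50).
#' @return `data.frame` with `start` (1-based window start), `width`, and
#'   `density` (matches per nt).
#' @export
motifDensity <- function(positions, transcriptLength, window = 300,
                         step = 50) {
  stopifnot(window >= step, step >= 1)
  starts <- seq(1L, transcriptLength, by = step)
  widths <- pmin(window, transcriptLength - starts + 1L)
  counts <- vapply(seq_along(starts), function(i)
    sum(positions >= starts[i] & positions < starts[i] + window), 1L)
  data.frame(start = starts, width = widths, density = counts / widths)
}

#' Mean spacing between motif occurrences
#'
#' Sequence length divided by the number of motif matches -- the average
#' number of nt per motif. The m6A consensus DRACH occurs about every 54 nt
#' along a typical transcript, far denser than actual methylation sites.
#'
#' @inheritParams scanMotif
#' @return nt per motif (numeric scalar).
#' @examples
#' \dontrun{meanMotifSpacing(txSeq, "DRACH")}
#' @export
meanMotifSpacing <- function(sequence, motif) {
  if (is.character(sequence))
    sequence <- DNAString(chartr("Uu", "Tt", toupper(sequence)))
  n <- length(scanMotif(sequence, motif))
  if (n == 0L)
    stop("no motif matches: mean spacing undefined")
  length(sequence) / n
}

#' Write motif matches as BED
#'
#' @param positions 1-based match starts.
#' @param motifLength match width in nt.
#' @param file output BED path.
#' @param transcriptName chrom field.
#' @param motif name field value.
#' @export
writeMotifBed <- function(positions, motifLength, file,
                          transcriptName = "transcript", motif = "motif") {
  ir <- IRanges(positions, width = motifLength)
  names(ir) <- rep(motif, length(ir))
  writeBedAnnotations(ir, file, transcriptName)
}
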