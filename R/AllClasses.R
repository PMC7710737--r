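#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors isSorted
NULL

#' TranscriptModel: a mature-transcript mini-genome coordinate system
#'
#' A `TranscriptModel` defines the coordinate system of a mature (intron-free)
#' transcript built from exon blocks on a genome, together with annotations of
#' tandem-repeat units and named domains given in transcript coordinates.
#' All downstream analyses (chimera calling, enrichment profiles, domain
#' quantification, crosslink clustering) operate in this transcript space.
#'
#' Coordinates are 1-based closed intervals ([IRanges::IRanges]); on-disk BED
#' interfaces use the usual 0-based half-open BED convention.
#'
#' @slot name transcript identifier.
#' @slot strand `"+"` or `"-"`; minus-strand models are reverse-complemented
#'   at sequence-build time, and transcript coordinates run 5' to 3' on the
#'   mature RNA.
#' @slot exons [IRanges::IRanges] of exon blocks in genomic coordinates,
#'   sorted and non-overlapping.
#' @slot repeats named list of [IRanges::IRanges], each the unit intervals of
#'   one tandem repeat, in transcript coordinates.
#' @slot domains named [IRanges::IRanges] of transcript domains (for example
#'   m6A domains), in transcript coordinates.
#'
#' @seealso [TranscriptModel()], [buildTranscriptSeq()],
#'   [liftGenomeToTranscript()]
#' @export
setClass("TranscriptModel",
  slots = c(
    name = "character",
    strand = "character",
    exons = "IRanges",
    repeats = "list",
    domains = "IRanges"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  ex <- object@exons
  if (length(ex) == 0L) {
    msg <- c(msg, "at least one exon is required")
  } else {
    if (any(start(ex) < 1L))
      msg <- c(msg, "exon starts must be >= 1")
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted by start")
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and separated")
  }
  L <- sum(width(ex))
  checkTx <- function(ir, what) {
    if (length(ir) && (any(start(ir) < 1L) || any(end(ir) > L)))
      sprintf("%s intervals must lie within [1, %d]", what, L)
    else NULL
  }
  if (length(object@repeats)) {
    if (is.null(names(object@repeats)) || any(!nzchar(names(object@repeats))))
      msg <- c(msg, "'repeats' must be a named list")
    for (nm in names(object@repeats)) {
      ir <- object@repeats[[nm]]
      if (!is(ir, "IRanges")) {
        msg <- c(msg, sprintf("repeats[[\"%s\"]] must be an IRanges", nm))
      } else {
        msg <- c(msg, checkTx(ir, sprintf("repeat \"%s\" unit", nm)))
      }
    }
  }
  msg <- c(msg, checkTx(object@domains, "domain"))
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param name transcript identifier.
#' @param exons [IRanges::IRanges] of exon blocks in genomic coordinates
#'   (1-based closed), sorted and non-overlapping.
#' @param strand `"+"` (default) or `"-"`.
#' @param repeats named list of [IRanges::IRanges] of repeat-unit intervals in
#'   transcript coordinates.
#' @param domains named [IRanges::IRanges] of domains in transcript
#'   coordinates.
#' @return a [TranscriptModel-class] object.
#' @examples
#' m <- TranscriptModel("tx", IRanges::IRanges(c(101, 301), c(200, 400)))
#' transcriptLength(m)  # 200
#' @export
TranscriptModel <- function(name, exons, strand = "+",
                            repeats = list(), domains = IRanges()) {
  new("TranscriptModel", name = name, strand = strand, exons = exons,
      repeats = repeats, domains = domains)
}

#' @describeIn TranscriptModel length of the mature transcript in nt
#'   (sum of exon widths).
#' @param model a [TranscriptModel-class].
#' @export
transcriptLength <- function(model) {
  stopifnot(is(model, "TranscriptModel"))
  sum(width(model@exons))
}

#' @describeIn TranscriptModel exon blocks (genomic [IRanges::IRanges]).
#' @export
exonBlocks <- function(model) model@exons

#' @describeIn TranscriptModel named list of repeat-unit [IRanges::IRanges]
#'   in transcript coordinates.
#' @export
repeatUnits <- function(model) model@repeats

#' @describeIn TranscriptModel named [IRanges::IRanges] of transcript domains.
#' @export
transcriptDomains <- function(model) model@domains

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel \"%s\" (%s strand)\n", object@name,
              object@strand))
  cat(sprintf("  %d exon(s), mature length %d nt\n", length(object@exons),
              transcriptLength(object)))
  if (length(object@repeats))
    cat(sprintf("  repeats: %s\n", paste(sprintf("%s (%d units)",
        names(object@repeats), lengths(object@repeats)), collapse = ", ")))
  if (length(object@domains))
    cat(sprintf("  domains: %s\n",
                paste(names(object@domains), collapse = ", ")))
  invisible(object)
})

#' LiftChain: block map between two transcript coordinate systems
#'
#' An alignment chain of equal-width blocks mapping intervals from a source
#' transcript to a homologous target transcript (for example mouse Xist to
#' human XIST). Blocks are non-overlapping and increase monotonically on both
#' sides; bases falling between blocks are unmapped.
#'
#' @slot source,target [IRanges::IRanges] of paired blocks (1-based closed);
#'   `width(source) == width(target)` blockwise.
#' @slot sourceName,targetName coordinate-system labels.
#' @seealso [LiftChain()], [liftViaChain()], [readChain()]
#' @export
setClass("LiftChain",
  slots = c(
    source = "IRanges",
    target = "IRanges",
    sourceName = "character",
    targetName = "character"
  )
)

setValidity("LiftChain", function(object) {
  msg <- character()
  s <- object@source; t <- object@target
  if (length(s) != length(t))
    msg <- c(msg, "source and target must have the same number of blocks")
  else if (length(s)) {
    if (any(width(s) != width(t)))
      msg <- c(msg, "paired blocks must have equal widths")
    mono <- function(ir) length(ir) < 2L ||
      all(start(ir)[-1L] > end(ir)[-length(ir)])
    if (!mono(s)) msg <- c(msg, "source blocks must be increasing and disjoint")
    if (!mono(t)) msg <- c(msg, "target blocks must be increasing and disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LiftChain
#'
#' @param source,target [IRanges::IRanges] of paired equal-width blocks.
#' @param sourceName,targetName labels for the two coordinate systems.
#' @return a [LiftChain-class].
#' @examples
#' ch <- LiftChain(IRanges::IRanges(1, 100), IRanges::IRanges(201, 300))
#' liftViaChain(IRanges::IRanges(11, 20), ch)
#' @export
LiftChain <- function(source, target, sourceName = "source",
                      targetName = "target") {
  new("LiftChain", source = source, target = target,
      sourceName = sourceName, targetName = targetName)
}

setMethod("show", "LiftChain", function(object) {
  cat(sprintf("LiftChain %s -> %s: %d block(s), %d nt aligned\n",
              object@sourceName, object@targetName, length(object@source),
              sum(width(object@source))))
  invisible(object)
})

#' EnrichmentProfile: windowed, input-normalized binding profile
#'
#' One sample's IP-over-input enrichment along the transcript in fixed
#' windows, rescaled so that a chosen quantile (default the 25th percentile)
#' of the profile equals a fixed anchor value (default 0.1). Anchoring to a
#' low quantile removes library-size effects while leaving profile shape
#' untouched: multiplying the raw sample coverage by any positive constant
#' yields the identical profile.
#'
#' @slot values normalized enrichment per window (all `>= 0`).
#' @slot window window width in nt.
#' @slot sampleId,protein sample annotations (may be empty strings).
#' @slot anchorPercentile percentile (0-100) pinned during scaling.
#' @slot anchorValue value the anchor percentile is pinned to.
#' @slot scaleFactor the multiplicative constant that was applied.
#' @seealso [normalizeProfile()], [binCoverage()]
#' @export
setClass("EnrichmentProfile",
  slots = c(
    values = "numeric",
    window = "integer",
    sampleId = "character",
    protein = "character",
    anchorPercentile = "numeric",
    anchorValue = "numeric",
    scaleFactor = "numeric"
  )
)

setValidity("EnrichmentProfile", function(object) {
  msg <- character()
  if (!length(object@values))
    msg <- c(msg, "'values' must be non-empty")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "'values' must be finite and >= 0")
  if (object@window < 1L)
    msg <- c(msg, "'window' must be >= 1")
  q <- stats::quantile(object@values, object@anchorPercentile / 100,
                       names = FALSE, type = 7)
  if (abs(q - object@anchorValue) > 1e-6 * max(1, object@anchorValue))
    msg <- c(msg, "anchor percentile of 'values' must equal 'anchorValue'")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentProfile the normalized per-window values.
#' @param profile an [EnrichmentProfile-class].
#' @export
profileValues <- function(profile) {
  stopifnot(is(profile, "EnrichmentProfile"))
  profile@values
}

setMethod("show", "EnrichmentProfile", function(object) {
  cat(sprintf(
    "EnrichmentProfile %s%s: %d windows of %d nt (P%g anchored at %g)\n",
    object@sampleId,
    if (nzchar(object@protein)) sprintf(" [%s]", object@protein) else "",
    length(object@values), object@window, object@anchorPercentile,
    object@anchorValue))
  invisible(object)
})
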