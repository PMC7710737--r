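#' Bin per-nucleotide coverage into fixed windows
#'
#' Each bin is the arithmetic mean of the per-nt coverage over one window;
#' the final window may be shorter and is averaged over its actual width.
#'
#' @param coverage numeric per-nt coverage vector.
#' @param window window width in nt (default 100).
#' @return numeric vector of length `ceiling(length(coverage) / window)`.
#' @examples
#' binCoverage(c(rep(0, 100), rep(2, 100)), 100)  # c(0, 2)
#' @export
binCoverage <- function(coverage, window = 100) {
  if (!length(coverage)) stop("empty coverage vector")
  stopifnot(window >= 1)
  idx <- ceiling(seq_along(coverage) / window)
  as.numeric(tapply(coverage, idx, mean))
}

#' Normalize a binned sample profile against the input average
#'
#' The per-window enrichment ratio is
#' `(sample + pseudocount) / (input + pseudocount)`, computed against the
#' average of the input controls in the same windows. Because IP library
#' depth is arbitrary, the profile is then rescaled by a single
#' multiplicative constant so that its `anchorPercentile` quantile
#' (linear-interpolation definition) equals `anchorValue` -- by default the
#' 25th percentile is set to 0.1. Anchoring a low quantile equalizes the
#' non-enriched background across samples so that profile shapes are
#' comparable.
#'
#' @param sampleBins,inputMeanBins equal-length binned coverage vectors.
#' @param pseudocount added to both numerator and denominator (default 1
#'   read per window) so zero-input windows stay finite.
#' @param anchorPercentile percentile (0-100) to pin (default 25).
#' @param anchorValue value it is pinned to (default 0.1).
#' @param window,sampleId,protein metadata carried into the result.
#' @return an [EnrichmentProfile-class].
#' @examples
#' p <- normalizeProfile(c(1, 2, 3, 4), rep(1, 4), pseudocount = 0)
#' profileValues(p)  # 25th percentile of ratios (1.75) rescaled to 0.1
#' @export
normalizeProfile <- function(sampleBins, inputMeanBins, pseudocount = 1,
                             anchorPercentile = 25, anchorValue = 0.1,
                             window = 100, sampleId = "", protein = "") {
  if (length(sampleBins) != length(inputMeanBins))
    stop("sample and input bin vectors must have equal length")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (all(sampleBins == 0))
    stop("degenerate profile: sample has no coverage")
  ratio <- (sampleBins + pseudocount) / (inputMeanBins + pseudocount)
  if (any(!is.finite(ratio)))
    stop("non-finite enrichment ratio; use a positive pseudocount")
  q <- stats::quantile(ratio, anchorPercentile / 100, names = FALSE, type = 7)
  if (q <= 0)
    stop("anchor quantile of the ratio profile is zero; cannot rescale")
  s <- anchorValue / q
  new("EnrichmentProfile", values = ratio * s, window = as.integer(window),
      sampleId = sampleId, protein = protein,
      anchorPercentile = anchorPercentile, anchorValue = anchorValue,
      scaleFactor = s)
}

# Accept a list of EnrichmentProfile or a plain samples x windows matrix.
profileMatrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  vals <- lapply(profiles, profileValues)
  if (length(unique(lengths(vals))) != 1L)
    stop("profiles must have equal length")
  m <- do.call(rbind, vals)
  ids <- vapply(profiles, function(p) p@sampleId, character(1))
  if (all(nzchar(ids))) rownames(m) <- ids
  m
}

#' Cluster binding profiles hierarchically
#'
#' Agglomerative clustering of samples by profile shape. The default
#' distance is `1 - Pearson correlation` between profiles, so samples group
#' by where they bind rather than how strongly; linkage is average (UPGMA).
#' A constant profile has no defined correlation and is assigned the maximum
#' distance (2) to every other sample, with a warning.
#'
#' @param profiles list of [EnrichmentProfile-class] or a samples-by-windows
#'   matrix with rownames as sample ids.
#' @param distance `"pearson"` (1 - r, default), `"spearman"` (1 - rho) or
#'   `"euclidean"`.
#' @param linkage an [stats::hclust] method (default `"average"`).
#' @param k if given, the dendrogram is also cut into `k` flat clusters.
#' @param log2 log2-transform values (with +1 offset) before clustering.
#' @return list with `hclust` (the merge tree), `dist` (the distance
#'   matrix), and `clusters` (named integer vector, only when `k` is given).
#' @export
clusterProfiles <- function(profiles, distance = c("pearson", "spearman",
                                                   "euclidean"),
                            linkage = "average", k = NULL, log2 = FALSE) {
  m <- profileMatrix(profiles)
  if (nrow(m) < 2L) stop("need >= 2 profiles to cluster")
  distance <- match.arg(distance)
  if (log2) m <- log2(m + 1)
  if (distance == "euclidean") {
    d <- stats::dist(m)
  } else {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
      warning("constant profile(s) assigned maximal correlation distance: ",
              paste(rownames(m)[sds == 0], collapse = ", "))
    cc <- suppressWarnings(stats::cor(t(m), method = distance))
    cc[!is.finite(cc)] <- -1  # constant profiles: maximal distance
    d <- stats::as.dist(1 - cc)
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, dist = d)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Write a profile dendrogram in Newick format
#'
#' @param hclust an [stats::hclust] tree (e.g. from [clusterProfiles()]).
#' @param file output path.
#' @importFrom ape as.phylo write.tree
#' @export
writeDendrogramNewick <- function(hclust, file) {
  ape::write.tree(ape::as.phylo(hclust), file = file)
  invisible(file)
}

#' Principal component analysis of binding profiles
#'
#' PCA on the samples-by-windows profile matrix: columns (windows) are mean
#' centered -- the removed mean profile is reported as its own track -- with
#' no variance scaling, and components come from the singular value
#' decomposition. Components are oriented so that each one's
#' largest-magnitude loading is positive, making runs deterministic.
#' Variance-explained fractions sum to 1 over all returned components.
#'
#' @param profiles list of [EnrichmentProfile-class] or samples-by-windows
#'   matrix.
#' @param nComponents number of leading components to keep (default all).
#' @return list with `mean` (the centered-out mean profile), `components`
#'   (windows-by-k loadings), `scores` (samples-by-k), and
#'   `variance_explained` (length-k fractions).
#' @export
pcaProfiles <- function(profiles, nComponents = NULL) {
  m <- profileMatrix(profiles)
  if (nrow(m) < 2L) stop("need >= 2 samples for PCA")
  mu <- colMeans(m)
  x <- sweep(m, 2L, mu)
  if (all(abs(x) < 1e-12))
    stop("centered profile matrix has rank 0 (all samples identical)")
  sv <- svd(x)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]; u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_along(d)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  ve <- d^2 / sum(d^2)
  kk <- if (is.null(nComponents)) length(d) else min(nComponents, length(d))
  scores <- u[, seq_len(kk), drop = FALSE] %*% diag(d[seq_len(kk)], kk)
  rownames(scores) <- rownames(m)
  colnames(scores) <- sprintf("PC%d", seq_len(kk))
  comp <- v[, seq_len(kk), drop = FALSE]
  colnames(comp) <- sprintf("PC%d", seq_len(kk))
  list(mean = mu, components = comp, scores = scores,
       variance_explained = ve[seq_len(kk)])
}

#' Spearman rank correlation between two profiles
#'
#' Rank correlation with midrank ties; the two-sided p-value uses the
#' t-distribution approximation. Constant input has no defined rank
#' correlation and is flagged rather than silently returned.
#'
#' @param a,b equal-length numeric vectors (length >= 4).
#' @return list with `rho`, `p_value`, and `defined` (FALSE when either
#'   input is constant, in which case `rho` and `p_value` are `NA`).
#' @examples
#' correlateProfiles(1:5, c(2, 1, 4, 3, 5))$rho  # 0.7
#' @export
correlateProfiles <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 4L) stop("need >= 4 windows for rank correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant profile: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, defined = TRUE)
}

#' Read a per-nt coverage track (bedGraph or 2-column TSV)
#'
#' bedGraph intervals (0-based half-open) are expanded to a per-nt vector;
#' a headerless 2-column TSV is read as (position, value) with 1-based
#' positions.
#'
#' @param file path to the track.
#' @param transcriptLength output vector length.
#' @param format `"bedGraph"` (default) or `"tsv"`.
#' @return numeric vector of length `transcriptLength`.
#' @export
readCoverageTrack <- function(file, transcriptLength,
                              format = c("bedGraph", "tsv")) {
  format <- match.arg(format)
  cov <- numeric(transcriptLength)
  if (format == "bedGraph") {
    gr <- rtracklayer::import(file, format = "bedGraph")
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      cov[s:min(e, transcriptLength)] <- gr$score[i]
    }
  } else {
    tab <- utils::read.table(file, header = FALSE, sep = "\t")
    cov[tab[[1L]]] <- tab[[2L]]
  }
  cov
}

#' Write a per-nt coverage vector as bedGraph
#'
#' Runs of equal value are merged into intervals; zero runs are skipped.
#'
#' @param coverage numeric per-nt vector.
#' @param file output path.
#' @param transcriptName chrom field value.
#' @export
writeCoverageTrack <- function(coverage, file, transcriptName = "transcript") {
  r <- rle(coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(transcriptName,
                               IRanges(starts[keep], ends[keep]),
                               score = r$values[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}
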