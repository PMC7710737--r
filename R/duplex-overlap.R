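#' Duplex-group tables
#'
#' A duplex group (DG) is a pair of arm intervals on the transcript
#' supported by gapped/chimeric reads, representing an RNA duplex (from
#' psoralen crosslinking data) or a ligation anchor pair. In memory a DG set
#' is a `data.frame` with columns `id`, `l_start`, `l_end`, `r_start`,
#' `r_end` (1-based closed, left arm 5' of right arm) and `support`; on disk
#' it is a 6-column TSV in 0-based half-open coordinates.
#'
#' @param file path to the DG TSV.
#' @return [readDgTable()] returns the validated DG `data.frame`.
#' @export
readDgTable <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("id", "l_start", "l_end", "r_start", "r_end", "support")
  if (!all(need %in% names(tab)))
    stop("DG table must have columns: ", paste(need, collapse = ", "))
  tab$l_start <- tab$l_start + 1L
  tab$r_start <- tab$r_start + 1L
  validateDgs(tab)
  tab
}

#' @rdname readDgTable
#' @param dgs in-memory DG table (1-based closed).
#' @export
writeDgTable <- function(dgs, file) {
  out <- dgs[, c("id", "l_start", "l_end", "r_start", "r_end", "support")]
  out$l_start <- out$l_start - 1L
  out$r_start <- out$r_start - 1L
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname readDgTable
#' @param transcriptLength if given, arms are checked against
#'   `[1, transcriptLength]`.
#' @export
validateDgs <- function(dgs, transcriptLength = NULL) {
  checkInterval(dgs$l_start, dgs$l_end, "left arm")
  checkInterval(dgs$r_start, dgs$r_end, "right arm")
  if (any(dgs$l_end >= dgs$r_start))
    stop("left arm must lie entirely 5' of (and not overlap) the right arm")
  if (any(dgs$l_start < 1L))
    stop("arm coordinates must be >= 1")
  if (!is.null(transcriptLength) && any(dgs$r_end > transcriptLength))
    stop("arm outside transcript bounds [1, ", transcriptLength, "]")
  invisible(TRUE)
}

#' Fraction of query duplex groups overlapping a reference set
#'
#' A query DG overlaps the reference set when at least one reference DG
#' intersects it on both arms: left arm with left arm and right arm with
#' right arm (arms are stored sorted, so arm order is fixed). Any overlap of
#' at least `minOverlap` nt per arm counts.
#'
#' @param query,reference DG `data.frame`s in the same coordinate space.
#' @param minOverlap minimum per-arm overlap in nt (default 1).
#' @return fraction of query DGs matched, in `[0, 1]`.
#' @export
dgOverlapFraction <- function(query, reference, minOverlap = 1) {
  if (nrow(query) == 0L) stop("empty query DG set")
  if (nrow(reference) == 0L) return(0)
  matched <- dgMatchedMask(query$l_start, query$l_end, query$r_start,
                           query$r_end, reference, minOverlap)
  mean(matched)
}

# Vectorized core: for parallel arm-coordinate vectors (possibly pooled over
# many shuffles), TRUE where >= 1 reference DG overlaps both arms.
dgMatchedMask <- function(ls, le, rs, re, reference, minOverlap = 1) {
  # overlap width of [a1,a2] and [b1,b2] is min(a2,b2) - max(a1,b1) + 1
  oL <- outer(le, reference$l_end, pmin) - outer(ls, reference$l_start, pmax) + 1
  oR <- outer(re, reference$r_end, pmin) - outer(rs, reference$r_start, pmax) + 1
  hit <- oL >= minOverlap & oR >= minOverlap
  rowSums(hit) > 0L
}

#' Shuffle duplex groups along the transcript
#'
#' The length-preserving null model for DG co-location: each DG keeps its
#' left-arm width, right-arm width and inter-arm gap (hence its outer span),
#' and the whole unit is placed uniformly at random along the transcript.
#' Preserving the gap keeps the structural length scale of each duplex, the
#' conservative null when asking whether two sets of duplexes co-locate.
#'
#' @param dgs DG `data.frame`.
#' @param transcriptLength transcript length in nt.
#' @param seed optional integer for reproducibility (RNG state is restored
#'   afterwards).
#' @param freeArms if `TRUE`, the two arms are instead placed independently
#'   (gap not preserved; arm order re-sorted), for sensitivity analysis.
#' @return a DG `data.frame` with the same ids, widths and gaps, new
#'   positions.
#' @export
shuffleDgs <- function(dgs, transcriptLength, seed = NULL, freeArms = FALSE) {
  lw <- dgs$l_end - dgs$l_start + 1L
  rw <- dgs$r_end - dgs$r_start + 1L
  gap <- dgs$r_start - dgs$l_end - 1L
  span <- lw + gap + rw
  if (any(span > transcriptLength))
    stop("DG outer span exceeds transcript length")
  withSeed(seed, {
    out <- dgs
    if (freeArms) {
      s1 <- sampleStarts(lw, transcriptLength)
      s2 <- sampleStarts(rw, transcriptLength)
      a1s <- pmin(s1, s2); a2s <- pmax(s1, s2)
      w1 <- ifelse(s1 <= s2, lw, rw); w2 <- ifelse(s1 <= s2, rw, lw)
      out$l_start <- a1s; out$l_end <- a1s + w1 - 1L
      out$r_start <- a2s; out$r_end <- a2s + w2 - 1L
    } else {
      s <- sampleStarts(span, transcriptLength)
      out$l_start <- s
      out$l_end <- s + lw - 1L
      out$r_start <- s + lw + gap
      out$r_end <- s + span - 1L
    }
    out
  })
}

# Uniform integer starts so that an interval of width w fits in [1, L].
sampleStarts <- function(w, L) {
  upper <- L - w + 1L
  as.integer(1L + floor(stats::runif(length(w)) * upper))
}

#' Permutation test for duplex-group set overlap
#'
#' Shuffles the query DG set `nShuffles` times with [shuffleDgs()] and
#' compares each shuffled overlap fraction with the observed one. The
#' p-value uses the add-one (Davison-Hinkley) correction
#' `p = (1 + #\{shuffled >= observed\}) / (nShuffles + 1)`, so it is never
#' exactly zero -- with 1000 shuffles and no shuffled set reaching the
#' observed overlap, `p = 1/1001 < 0.001`.
#'
#' @inheritParams dgOverlapFraction
#' @param transcriptLength transcript length in nt.
#' @param nShuffles number of shuffles (default 1000).
#' @param seed optional integer seed for the shuffle schedule.
#' @param freeArms passed to [shuffleDgs()].
#' @return list of class `OverlapResult`: `observed` (fraction),
#'   `shuffled` (length-`nShuffles` fractions), `p_value`, `n_shuffles`.
#' @export
permutationPvalue <- function(query, reference, transcriptLength,
                              nShuffles = 1000, seed = NULL,
                              minOverlap = 1, freeArms = FALSE) {
  if (nrow(query) == 0L || nrow(reference) == 0L)
    stop("empty DG set")
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  observed <- dgOverlapFraction(query, reference, minOverlap)
  lw <- query$l_end - query$l_start + 1L
  rw <- query$r_end - query$r_start + 1L
  gap <- query$r_start - query$l_end - 1L
  span <- lw + gap + rw
  if (any(span > transcriptLength))
    stop("DG outer span exceeds transcript length")
  nq <- nrow(query)
  shuffled <- withSeed(seed, {
    if (freeArms) {
      vapply(seq_len(nShuffles), function(i) {
        sh <- shuffleDgs(query, transcriptLength, freeArms = TRUE)
        dgOverlapFraction(sh, reference, minOverlap)
      }, numeric(1))
    } else {
      # vectorized: one uniform start per (shuffle, query DG)
      u <- matrix(as.integer(1L + floor(stats::runif(nShuffles * nq) *
                             rep(transcriptLength - span + 1L, each = nShuffles))),
                  nrow = nShuffles)
      frac <- numeric(nShuffles)
      for (s in seq_len(nShuffles)) {
        st <- u[s, ]
        m <- dgMatchedMask(st, st + lw - 1L, st + lw + gap,
                           st + span - 1L, reference, minOverlap)
        frac[s] <- mean(m)
      }
      frac
    }
  })
  p <- (1 + sum(shuffled >= observed)) / (nShuffles + 1)
  structure(list(observed = observed, shuffled = shuffled, p_value = p,
                 n_shuffles = nShuffles),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "DG overlap: observed fraction %.3f; p = %.4g (%d shuffles, max shuffled %.3f)\n",
    x$observed, x$p_value, x$n_shuffles, max(x$shuffled)))
  invisible(x)
}

#' Write an OverlapResult as a JSON report (plus optional shuffle TSV)
#'
#' @param result an `OverlapResult` from [permutationPvalue()].
#' @param file JSON output path.
#' @param shuffleFile optional TSV path for the shuffled fractions.
#' @importFrom jsonlite write_json
#' @export
writeOverlapResult <- function(result, file, shuffleFile = NULL) {
  jsonlite::write_json(
    list(observed_overlap_fraction = result$observed,
         p_value = result$p_value,
         n_shuffles = result$n_shuffles,
         shuffled_mean = mean(result$shuffled),
         shuffled_max = max(result$shuffled)),
    file, auto_unbox = TRUE, digits = NA)
  if (!is.null(shuffleFile))
    utils::write.table(data.frame(shuffle = seq_along(result$shuffled),
                                  overlap_fraction = result$shuffled),
                       shuffleFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(file)
}
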