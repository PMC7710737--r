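# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its arguments: a fixed seed gives byte-identical output
# and the caller's RNG state is left untouched.

#' Simulate a transcript with tandem repeats and named domains
#'
#' Generates a random background sequence of the requested length and GC
#' content, then overwrites tandem copies of a randomly drawn repeat unit at
#' each requested insertion position. Repeat-unit and domain annotations are
#' returned in transcript coordinates ready for BED export.
#'
#' @param transcriptLength length in nt (default 19000, the scale of a large
#'   architectural lncRNA).
#' @param gc GC content of the background (default 0.5).
#' @param repeats list of repeat specs, each a list with `name`,
#'   `unitLength`, `copies`, `at` (1-based start of the first unit).
#' @param domains named list of `c(start, end)` domain intervals.
#' @param seed integer seed.
#' @return list with `sequence` ([Biostrings::DNAString]), `model` (a
#'   single-exon [TranscriptModel-class] carrying the annotations), and
#'   `repeatUnits` (named list of [IRanges::IRanges]).
#' @examples
#' tx <- simulateTranscript(2000, repeats = list(
#'   list(name = "A", unitLength = 24, copies = 8, at = 301)), seed = 1)
#' @importFrom Biostrings DNAString
#' @export
simulateTranscript <- function(transcriptLength = 19000, gc = 0.5,
                               repeats = list(), domains = list(),
                               seed = 1) {
  stopifnot(transcriptLength >= 1, gc >= 0, gc <= 1)
  withSeed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    base <- sample(names(p), transcriptLength, replace = TRUE, prob = p)
    units <- list()
    occupied <- IRanges()
    for (rp in repeats) {
      w <- rp$unitLength * rp$copies
      s <- rp$at
      if (s < 1L || s + w - 1L > transcriptLength)
        stop("repeat \"", rp$name, "\" extends outside the transcript")
      footprint <- IRanges(s, s + w - 1L)
      if (length(occupied) &&
          any(start(footprint) <= end(occupied) &
              end(footprint) >= start(occupied)))
        stop("overlapping repeat insertions")
      occupied <- c(occupied, footprint)
      unit <- sample(names(p), rp$unitLength, replace = TRUE, prob = p)
      base[s:(s + w - 1L)] <- rep(unit, rp$copies)
      units[[rp$name]] <- IRanges(start = s + rp$unitLength *
                                    (seq_len(rp$copies) - 1L),
                                  width = rp$unitLength)
    }
    dom <- if (length(domains)) {
      ir <- IRanges(vapply(domains, `[`, 1, 1),
                    vapply(domains, `[`, 1, 2))
      names(ir) <- names(domains)
      ir
    } else IRanges()
    model <- TranscriptModel("synthetic", IRanges(1L, transcriptLength),
                             repeats = units, domains = dom)
    list(sequence = DNAString(paste(base, collapse = "")), model = model,
         repeatUnits = units)
  })
}

#' Simulate paired-end RIP tag pairs with planted chimeras
#'
#' Most pairs are single sonicated fragments: a uniform start, a truncated
#' normal fragment length (mean 200 nt, sd 80, minimum 62 -- the library's
#' 100-400 nt bulk), and one 31-nt tag at each fragment end. A fraction
#' `chimeraRate` of pairs are proximity-ligation chimeras: the two tags fall
#' into the two arms of a planted anchor pair drawn uniformly from
#' `anchors`.
#'
#' @param n number of pairs.
#' @param transcriptLength transcript length in nt.
#' @param anchors list of planted anchor pairs, each a list with `left` and
#'   `right` `c(start, end)` intervals (each at least `tagLength` wide).
#' @param chimeraRate fraction of chimeric pairs (default 0.02).
#' @param fragMean,fragSd,fragMin truncated-normal fragment length
#'   parameters (defaults 200, 80, 62).
#' @param tagLength sequenced tag length (default 31).
#' @param seed integer seed.
#' @return pair `data.frame` (`read_id`, `start1`, `end1`, `start2`, `end2`,
#'   1-based closed) with a logical ground-truth column `chimeric` and an
#'   integer `anchor` (index into `anchors`, `NA` for fragments).
#' @export
simulateFripPairs <- function(n, transcriptLength = 19000, anchors = list(),
                              chimeraRate = 0.02, fragMean = 200,
                              fragSd = 80, fragMin = 62, tagLength = 31,
                              seed = 1) {
  stopifnot(n >= 1, chimeraRate >= 0, chimeraRate <= 1,
            fragMin >= 2 * tagLength)
  if (chimeraRate > 0 && !length(anchors))
    stop("chimeraRate > 0 requires planted anchors")
  for (a in anchors) {
    if (a$left[2] - a$left[1] + 1 < tagLength ||
        a$right[2] - a$right[1] + 1 < tagLength)
      stop("anchor narrower than the tag length")
  }
  withSeed(seed, {
    chim <- stats::runif(n) < chimeraRate
    nf <- sum(!chim); nc <- sum(chim)
    len <- numeric(0)
    if (nf) {
      len <- stats::rnorm(nf, fragMean, fragSd)
      while (any(bad <- len < fragMin | len > transcriptLength))
        len[bad] <- stats::rnorm(sum(bad), fragMean, fragSd)
      len <- round(len)
    }
    start1 <- end1 <- start2 <- end2 <- integer(n)
    if (nf) {
      fs <- 1L + floor(stats::runif(nf) * (transcriptLength - len + 1))
      start1[!chim] <- as.integer(fs)
      end1[!chim] <- as.integer(fs + tagLength - 1L)
      start2[!chim] <- as.integer(fs + len - tagLength)
      end2[!chim] <- as.integer(fs + len - 1L)
    }
    if (nc) {
      ai <- sample.int(length(anchors), nc, replace = TRUE)
      ls <- vapply(anchors, function(a) a$left[1], 1)
      le <- vapply(anchors, function(a) a$left[2], 1)
      rs <- vapply(anchors, function(a) a$right[1], 1)
      re <- vapply(anchors, function(a) a$right[2], 1)
      t1 <- ls[ai] + floor(stats::runif(nc) * (le[ai] - ls[ai] - tagLength + 2))
      t2 <- rs[ai] + floor(stats::runif(nc) * (re[ai] - rs[ai] - tagLength + 2))
      start1[chim] <- as.integer(t1); end1[chim] <- as.integer(t1 + tagLength - 1L)
      start2[chim] <- as.integer(t2); end2[chim] <- as.integer(t2 + tagLength - 1L)
    }
    out <- data.frame(read_id = sprintf("pair_%07d", seq_len(n)),
                      start1 = start1, end1 = end1,
                      start2 = start2, end2 = end2,
                      chimeric = chim,
                      anchor = NA_integer_)
    if (nc) out$anchor[chim] <- as.integer(ai)
    out
  })
}

#' Simulate IP and input coverage with planted domain enrichment
#'
#' Input reads fall uniformly along the transcript; IP reads are multinomial
#' with per-nt weight 1 outside and `fold` inside each planted domain. Reads
#' are counted at single-nt resolution, so the returned vectors are per-nt
#' read counts summing to the library sizes.
#'
#' @param transcriptLength transcript length in nt.
#' @param domains named [IRanges::IRanges] (or list of `c(start, end)`).
#' @param folds numeric vector of per-domain enrichment folds, recycled.
#' @param ipReads,inputReads library sizes (default 50000 each).
#' @param seed integer seed.
#' @return list with `ip` and `input` per-nt count vectors.
#' @export
simulateIpInput <- function(transcriptLength = 19000, domains = IRanges(),
                            folds = numeric(), ipReads = 50000,
                            inputReads = 50000, seed = 1) {
  if (ipReads < 1 || inputReads < 1) stop("library sizes must be >= 1")
  if (is.list(domains) && !is(domains, "IRanges")) {
    ir <- IRanges(vapply(domains, `[`, 1, 1), vapply(domains, `[`, 1, 2))
    names(ir) <- names(domains)
    domains <- ir
  }
  folds <- rep_len(if (length(folds)) folds else 1, length(domains))
  w <- rep(1, transcriptLength)
  for (i in seq_along(domains))
    w[start(domains)[i]:end(domains)[i]] <- folds[i]
  withSeed(seed, {
    ip <- as.numeric(stats::rmultinom(1L, ipReads, w))
    input <- as.numeric(stats::rmultinom(1L, inputReads,
                                         rep(1, transcriptLength)))
    list(ip = ip, input = input)
  })
}

#' Simulate query and reference duplex-group sets with a shared fraction
#'
#' Reference DGs are placed at random with arm widths and inter-arm gaps
#' drawn from the given ranges. A fraction `sharedFraction` of query DGs are
#' jittered copies of randomly chosen reference DGs (each coordinate moved
#' by up to `jitter` nt); the rest are placed independently.
#'
#' @param nQuery,nReference set sizes.
#' @param sharedFraction fraction of query DGs copied from the reference.
#' @param transcriptLength transcript length in nt.
#' @param armWidthRange,gapRange integer ranges for arm width and inter-arm
#'   gap.
#' @param jitter maximum per-copy displacement in nt (default 10).
#' @param seed integer seed.
#' @return list with `query` and `reference` DG `data.frame`s; the query
#'   carries a logical ground-truth column `shared`.
#' @export
simulateDgSets <- function(nQuery = 100, nReference = 100,
                           sharedFraction = 0.5, transcriptLength = 19000,
                           armWidthRange = c(20, 40),
                           gapRange = c(200, 5000), jitter = 10, seed = 1) {
  stopifnot(sharedFraction >= 0, sharedFraction <= 1)
  randomDgs <- function(n, prefix) {
    lw <- sample(armWidthRange[1]:armWidthRange[2], n, replace = TRUE)
    rw <- sample(armWidthRange[1]:armWidthRange[2], n, replace = TRUE)
    gap <- sample(gapRange[1]:gapRange[2], n, replace = TRUE)
    span <- lw + gap + rw
    s <- 1L + floor(stats::runif(n) * (transcriptLength - span + 1))
    data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
               l_start = as.integer(s), l_end = as.integer(s + lw - 1),
               r_start = as.integer(s + lw + gap),
               r_end = as.integer(s + span - 1),
               support = sample(2:50, n, replace = TRUE))
  }
  withSeed(seed, {
    reference <- randomDgs(nReference, "ref")
    nShared <- round(sharedFraction * nQuery)
    query <- randomDgs(nQuery, "qry")
    query$shared <- FALSE
    if (nShared > 0) {
      src <- sample.int(nReference, nShared, replace = TRUE)
      idx <- seq_len(nShared)
      jit <- function(n) sample(seq(-jitter, jitter), n, replace = TRUE)
      query$l_start[idx] <- reference$l_start[src] + jit(nShared)
      query$l_end[idx] <- pmax(query$l_start[idx] + 1L,
                               reference$l_end[src] + jit(nShared))
      query$r_start[idx] <- pmax(query$l_end[idx] + 2L,
                                 reference$r_start[src] + jit(nShared))
      query$r_end[idx] <- pmax(query$r_start[idx] + 1L,
                               reference$r_end[src] + jit(nShared))
      query$l_start[idx] <- pmax(1L, query$l_start[idx])
      query$r_end[idx] <- pmin(as.integer(transcriptLength),
                               query$r_end[idx])
      query$shared[idx] <- TRUE
    }
    validateDgs(query, transcriptLength)
    validateDgs(reference, transcriptLength)
    list(query = query, reference = reference)
  })
}

#' Simulate two irCLIP replicate alignment tables
#'
#' Each planted crosslink position yields Poisson(`lambda`) reads per
#' replicate starting exactly 1 nt downstream of the crosslink (so the 1-nt
#' 5' shift of [crosslinkSites()] recovers the planted position). A fraction
#' `noiseRate` of each replicate's reads start uniformly along the
#' transcript instead.
#'
#' @param positions integer vector of planted crosslink positions (shared
#'   between replicates).
#' @param transcriptLength transcript length in nt.
#' @param lambda mean reads per crosslink site per replicate (default 20).
#' @param noiseRate fraction of uniform background reads (default 0.05).
#' @param readLength alignment length in nt (default 35).
#' @param seed integer seed.
#' @return list with `rep1` and `rep2` alignment `data.frame`s (`start`,
#'   `end`, 1-based closed).
#' @export
simulateIrclip <- function(positions, transcriptLength = 19000, lambda = 20,
                           noiseRate = 0.05, readLength = 35, seed = 1) {
  stopifnot(all(positions >= 1), all(positions < transcriptLength),
            noiseRate >= 0, noiseRate < 1)
  withSeed(seed, {
    oneRep <- function() {
      counts <- stats::rpois(length(positions), lambda)
      starts <- rep(positions + 1L, counts)
      nSignal <- length(starts)
      nNoise <- round(nSignal * noiseRate / (1 - noiseRate))
      if (nNoise > 0)
        starts <- c(starts, 1L + floor(stats::runif(nNoise) *
                                       (transcriptLength - readLength + 1)))
      starts <- as.integer(starts)
      data.frame(start = starts,
                 end = pmin(starts + readLength - 1L,
                            as.integer(transcriptLength)))
    }
    list(rep1 = oneRep(), rep2 = oneRep())
  })
}
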