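test_that("pair span is the inclusive outer distance and the class boundary is inclusive to short", {
  p <- data.frame(start1 = c(101, 101, 1), end1 = c(131, 131, 31),
                  start2 = c(301, 9001, 970), end2 = c(331, 9031, 1000))
  cls <- classifyPairs(p, longThreshold = 1000)
  expect_equal(cls$span, c(231L, 8931L, 1000L))
  expect_equal(cls$class, c("short", "long", "short"))

  # classification is invariant to swapping tag1/tag2
  swapped <- data.frame(start1 = p$start2, end1 = p$end2,
                        start2 = p$start1, end2 = p$end1)
  cls2 <- classifyPairs(swapped, longThreshold = 1000)
  expect_equal(cls2$span, cls$span)
  expect_equal(cls2$class, cls$class)

  expect_error(classifyPairs(data.frame(start1 = 10, end1 = 5,
                                        start2 = 1, end2 = 3)), "malformed")
  expect_error(classifyPairs(p, transcriptLength = 500), "bounds")
})

test_that("short + long counts always partition the sample", {
  set.seed(21)
  p <- simulateFripPairs(5000, 19000,
                         anchors = list(list(left = c(1000, 1200),
                                             right = c(8000, 8200))),
                         chimeraRate = 0.03, seed = 21)
  for (thr in c(300, 1000, 5000)) {
    cls <- classifyPairs(p, thr)
    expect_equal(sum(cls$class == "short") + sum(cls$class == "long"),
                 nrow(p))
  }
})

test_that("long-pair fraction counts long pairs over all pairs and rejects empty input", {
  mk <- function(n, nlong) {
    data.frame(start1 = rep(101, n), end1 = 131,
               start2 = c(rep(9001, nlong), rep(301, n - nlong)),
               end2 = c(rep(9031, nlong), rep(331, n - nlong)))
  }
  expect_equal(longPairFraction(mk(1000, 10)), 0.01)
  expect_equal(longPairFraction(mk(500, 0)), 0)
  expect_error(longPairFraction(mk(5, 0)[0, ]), "undefined")
})

test_that("long-group calling matches a single-linkage hclust oracle on random point clouds", {
  # oracle: hclust on Chebyshev distances of oriented midpoints, cut at the
  # link distance (single linkage <=> connected components at that radius)
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    ml <- sample(500:9000, n, TRUE)
    mr <- sample(10000:18000, n, TRUE)
    p <- data.frame(start1 = ml - 15, end1 = ml + 15,
                    start2 = mr - 15, end2 = mr + 15)
    link <- 400
    lg <- callLongGroups(p, linkDistance = link, minSupport = 1)
    d <- stats::dist(cbind(ml, mr), method = "maximum")
    oracle <- stats::cutree(stats::hclust(d, method = "single"), h = link)
    # same partition: membership vectors equal up to label permutation
    got <- integer(n)
    for (g in seq_len(nrow(lg))) got[lg$members[[g]]] <- g
    expect_equal(length(unique(oracle)), nrow(lg))
    # identical partitions: the cross-tabulation is a permutation matrix
    tab <- table(got, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("long-group calling recovers planted anchors and respects min support", {
  p3 <- data.frame(start1 = c(1000, 1050, 1080), end1 = c(1030, 1080, 1110),
                   start2 = c(8000, 8010, 8100), end2 = c(8030, 8040, 8130))
  lg <- callLongGroups(p3, linkDistance = 500, minSupport = 3)
  expect_equal(nrow(lg), 1L)
  expect_equal(lg$support, 3L)
  expect_equal(lg$left_start, 1000L)
  expect_equal(lg$right_end, 8130L)

  # two well-separated anchor pairs -> two groups
  p4 <- data.frame(start1 = c(1000, 1010, 3000, 3010),
                   end1 = c(1030, 1040, 3030, 3040),
                   start2 = c(8000, 8020, 6000, 6020),
                   end2 = c(8030, 8050, 6030, 6050))
  lg <- callLongGroups(p4, linkDistance = 500, minSupport = 2)
  expect_equal(nrow(lg), 2L)

  # below min support -> nothing
  expect_equal(nrow(callLongGroups(p3[1, ], minSupport = 2)), 0L)
  expect_equal(nrow(callLongGroups(p3[0, ])), 0L)

  # duplicate pairs are collapsed before support counting
  dup <- p3[c(1, 1, 1, 2), ]
  lg <- callLongGroups(dup, linkDistance = 500, minSupport = 3)
  expect_equal(nrow(lg), 0L)
})

test_that("fragment extension grows tags toward the fragment interior and clips at bounds", {
  p <- data.frame(start1 = 101, end1 = 131, start2 = 501, end2 = 531)
  ext <- extendToFragment(p, 194)
  expect_equal(ext$end1, 294L)     # tag1 extended downstream
  expect_equal(ext$start1, 101L)
  expect_equal(ext$start2, 338L)   # tag2 extended upstream
  expect_equal(ext$end2, 531L)

  # clipping at the transcript end
  pEnd <- data.frame(start1 = 18971, end1 = 19000,
                     start2 = 5, end2 = 35)
  ext <- extendToFragment(pEnd, 194, transcriptLength = 19000)
  expect_equal(ext$end1, 19000L)
  expect_equal(ext$start2, 1L)

  # tag wider than the fragment length: unchanged with a warning
  pWide <- data.frame(start1 = 101, end1 = 400, start2 = 501, end2 = 531)
  expect_warning(ext <- extendToFragment(pWide, 194), "wider")
  expect_equal(ext$end1, 400L)
})

test_that("LG/DG matching requires both anchors to hit arms, in either arm order", {
  lgs <- data.frame(lg_id = "LG1", left_start = 1000L, left_end = 1200L,
                    right_start = 8000L, right_end = 8200L)
  dgs <- data.frame(id = c("dg1", "dg2"),
                    l_start = c(1100L, 3000L), l_end = c(1150L, 3050L),
                    r_start = c(8100L, 5000L), r_end = c(8150L, 5050L),
                    support = 5L)
  rep1 <- lgDgOverlap(lgs, dgs, extension = 0)
  expect_equal(rep1$n_matched, 1L)
  expect_equal(rep1$dg_ids, "dg1")

  # arm-swapped duplex still matches (symmetry)
  swapped <- data.frame(id = "dgS", l_start = 8100L, l_end = 8150L,
                        r_start = 1100L, r_end = 1150L, support = 5L)
  expect_equal(lgDgOverlap(lgs, swapped, extension = 0)$n_matched, 1L)

  # disjoint -> no overlap
  far <- data.frame(id = "dgF", l_start = 2000L, l_end = 2050L,
                    r_start = 9000L, r_end = 9050L, support = 5L)
  expect_equal(lgDgOverlap(lgs, far, extension = 0)$n_matched, 0L)
  # ... unless extension bridges the gap
  expect_equal(lgDgOverlap(lgs, far, extension = 1000)$n_matched, 1L)
})

test_that("pair tables round-trip through the 0-based TSV format", {
  p <- data.frame(read_id = c("r1", "r2"),
                  start1 = c(101L, 5L), end1 = c(131L, 35L),
                  start2 = c(301L, 9001L), end2 = c(331L, 9031L))
  f <- tempfile(fileext = ".tsv")
  writePairTable(p, f)
  ondisk <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(ondisk$start1, c(100L, 4L))  # BED-style starts on disk
  back <- readPairTable(f)
  expect_equal(back$start1, p$start1)
  expect_equal(back$end2, p$end2)
})

test_that("tag coverage sums both tags and nothing else", {
  p <- data.frame(start1 = 11, end1 = 20, start2 = 31, end2 = 40)
  cov <- pairTagCoverage(p, 50)
  expect_equal(sum(cov), 20)
  expect_equal(unname(cov[15]), 1)
  expect_equal(unname(cov[25]), 0)
})
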