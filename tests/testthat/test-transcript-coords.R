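library(IRanges)

test_that("transcript sequence is the exon concatenation, reverse-complemented on minus strand", {
  genome <- "AAAAACCCCCGGGGG"
  mPlus <- TranscriptModel("tx", IRanges(c(1, 11), c(5, 15)))
  expect_equal(as.character(buildTranscriptSeq(mPlus, genome)), "AAAAAGGGGG")
  expect_equal(transcriptLength(mPlus), 10L)

  mMinus <- TranscriptModel("tx", IRanges(c(1, 11), c(5, 15)), strand = "-")
  expect_equal(as.character(buildTranscriptSeq(mMinus, genome)),
               revcompOracle("AAAAAGGGGG"))  # CCCCCTTTTT
  expect_equal(as.character(buildTranscriptSeq(mMinus, genome)),
               "CCCCCTTTTT")

  # exon outside the genome sequence
  mOut <- TranscriptModel("tx", IRanges(13, 20))
  expect_error(buildTranscriptSeq(mOut, genome), "outside")
})

test_that("model validity rejects unsorted or out-of-bounds annotation", {
  expect_error(TranscriptModel("tx", IRanges(c(11, 1), c(15, 5))), "sorted")
  expect_error(TranscriptModel("tx", IRanges(c(1, 3), c(5, 8))),
               "non-overlapping")
  expect_error(
    TranscriptModel("tx", IRanges(1, 10),
                    domains = IRanges(5, 20, names = "D1")),
    "within")
})

test_that("genome-to-transcript lift handles exonic, intron-spanning and intronic intervals", {
  m <- TranscriptModel("tx", IRanges(c(101, 301), c(200, 400)))
  res <- liftGenomeToTranscript(IRanges(c(151, 191, 211), c(160, 310, 290)), m)
  # fully inside exon 1
  expect_equal(res$start[1], 51L)
  expect_equal(res$end[1], 60L)
  expect_equal(res$mapped_fraction[1], 1)
  # spanning the intron: exonic portions concatenate to 91..110
  expect_equal(res$start[2], 91L)
  expect_equal(res$end[2], 110L)
  expect_equal(res$mapped_bases[2], 20L)
  # fully intronic -> unmapped
  expect_true(is.na(res$start[3]))
  expect_equal(res$mapped_fraction[3], 0)

  expect_error(liftGenomeToTranscript(IRanges(), m), NA)
  # zero-width (end < start) query is malformed
  expect_error(liftGenomeToTranscript(IRanges(10, 9), m), "width")
})

test_that("lift agrees with the per-base oracle on random intervals", {
  set.seed(11)
  exons <- cbind(c(51, 201, 501), c(120, 340, 620))
  m <- TranscriptModel("tx", IRanges(exons[, 1], exons[, 2]))
  for (i in 1:25) {
    s <- sample(1:650, 1); e <- s + sample(0:200, 1)
    res <- liftGenomeToTranscript(IRanges(s, min(e, 700)), m)
    tpos <- perBaseLiftOracle(s, min(e, 700), exons)
    if (length(tpos) == 0L) {
      expect_true(is.na(res$start))
    } else {
      expect_equal(res$start, min(tpos))
      expect_equal(res$end, max(tpos))
      expect_equal(res$mapped_bases, length(tpos))
    }
  }
})

test_that("round trip transcript -> genome -> transcript recovers exonic sub-intervals", {
  m <- TranscriptModel("tx", IRanges(c(101, 301, 601), c(200, 400, 650)))
  set.seed(7)
  L <- transcriptLength(m)
  for (i in 1:20) {
    s <- sample(seq_len(L - 1), 1); e <- sample(s:L, 1)
    gint <- liftTranscriptToGenome(IRanges(s, e), m)[[1]]
    # total bases conserved
    expect_equal(sum(width(gint)), e - s + 1L)
    # lifting each genomic piece back gives contiguous transcript pieces
    back <- liftGenomeToTranscript(gint, m)
    expect_true(all(back$mapped_fraction == 1))
    expect_equal(min(back$start), s)
    expect_equal(max(back$end), e)
    expect_equal(sum(back$mapped_bases), e - s + 1L)
  }
})

test_that("chain lifting maps through blocks, drops gap bases, identity chain is identity", {
  ident <- LiftChain(IRanges(1, 1000), IRanges(1, 1000))
  res <- liftViaChain(IRanges(11, 20), ident)
  expect_equal(res$start, 11L)
  expect_equal(res$end, 20L)
  expect_equal(res$mapped_fraction, 1)

  ch <- LiftChain(IRanges(1, 100), IRanges(201, 300))
  res <- liftViaChain(IRanges(11, 20), ch)
  expect_equal(unlist(res[1, c("start", "end")], use.names = FALSE),
               c(211L, 220L))

  # interval entirely inside a chain gap -> unmapped
  gapped <- LiftChain(IRanges(c(1, 201), c(100, 300)),
                      IRanges(c(1, 201), c(100, 300)))
  res <- liftViaChain(IRanges(120, 180), gapped)
  expect_true(is.na(res$start))

  # a partial lift reports mapped fraction and can be filtered
  res <- liftViaChain(IRanges(90, 210), gapped)
  expect_equal(res$mapped_bases, 21L)
  expect_lt(res$mapped_fraction, 0.5)
  expect_true(is.na(liftViaChain(IRanges(90, 210), gapped,
                                 minFraction = 0.5)$start))
})

test_that("identity chain preserves mapped base counts on tiling queries", {
  ch <- LiftChain(IRanges(c(1, 151), c(100, 400)),
                  IRanges(c(501, 701), c(600, 950)))
  tiles <- IRanges(start = seq(1, 391, by = 10), width = 10)
  res <- liftViaChain(tiles, ch)
  expect_equal(sum(res$mapped_bases), sum(width(ch@source)) -
                 0L)  # every aligned base covered exactly once by the tiling
})

test_that("chain validity enforces block geometry and TSV round trip preserves it", {
  expect_error(LiftChain(IRanges(1, 10), IRanges(1, 12)), "equal widths")
  expect_error(LiftChain(IRanges(c(1, 5), c(10, 20)),
                         IRanges(c(1, 5), c(10, 20))), "disjoint")
  ch <- LiftChain(IRanges(c(1, 201), c(100, 260)),
                  IRanges(c(51, 401), c(150, 460)))
  f <- tempfile(fileext = ".tsv")
  writeChain(ch, f)
  ch2 <- readChain(f)
  expect_equal(start(ch2@source), start(ch@source))
  expect_equal(end(ch2@target), end(ch@target))
})

test_that("lifting a DG table keeps arm geometry and drops unliftable groups", {
  dgs <- data.frame(id = c("a", "b"), l_start = c(10L, 500L),
                    l_end = c(30L, 520L), r_start = c(200L, 700L),
                    r_end = c(230L, 730L), support = 5L)
  ch <- LiftChain(IRanges(1, 300), IRanges(1001, 1300))
  lifted <- liftDgTable(dgs, ch)
  expect_equal(nrow(lifted), 1L)
  expect_equal(lifted$l_start, 1010L)
  expect_equal(lifted$r_end, 1230L)
})

test_that("BED annotation round trip preserves names and coordinates", {
  ir <- IRanges(c(301, 5001), c(700, 5500), names = c("D1", "D2"))
  f <- tempfile(fileext = ".bed")
  writeBedAnnotations(ir, f, "tx")
  back <- readBedAnnotations(f)
  expect_equal(start(back), start(ir))
  expect_equal(end(back), end(ir))
  expect_equal(names(back), names(ir))
})
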