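library(IRanges)

test_that("simulated transcripts are seed-deterministic with correct repeat annotation", {
  tx1 <- simulateTranscript(2000, repeats = list(
    list(name = "A", unitLength = 24, copies = 8, at = 301)), seed = 5)
  tx2 <- simulateTranscript(2000, repeats = list(
    list(name = "A", unitLength = 24, copies = 8, at = 301)), seed = 5)
  expect_equal(as.character(tx1$sequence), as.character(tx2$sequence))
  units <- tx1$repeatUnits$A
  expect_equal(length(units), 8L)
  expect_true(all(width(units) == 24))
  expect_equal(start(units)[1], 301L)
  # tandem copies are identical in sequence
  s <- as.character(tx1$sequence)
  expect_equal(substr(s, 301, 324), substr(s, 325, 348))

  expect_error(simulateTranscript(500, repeats = list(
    list(name = "A", unitLength = 100, copies = 3, at = 301))), "outside")
  expect_error(simulateTranscript(2000, repeats = list(
    list(name = "A", unitLength = 24, copies = 4, at = 301),
    list(name = "B", unitLength = 10, copies = 2, at = 310))), "overlapping")
})

test_that("background GC content tracks the requested value", {
  tx <- simulateTranscript(19000, gc = 0.4, seed = 7)
  s <- strsplit(as.character(tx$sequence), "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 0.02)
})

test_that("simulated RIP pairs respect the fragment model and planted chimera rate", {
  anchors <- list(list(left = c(1000, 1200), right = c(8000, 8200)))
  # rate 0: every span is a single fragment
  p0 <- simulateFripPairs(2000, 19000, chimeraRate = 0, seed = 11)
  expect_equal(nrow(p0), 2000L)
  cls <- classifyPairs(p0)
  expect_true(all(cls$span <= 1000))
  expect_true(all(cls$span >= 62))
  expect_true(all(cls$end1 - cls$start1 + 1 == 31))

  # chimeric tags land in the planted anchors
  p <- simulateFripPairs(5000, 19000, anchors, chimeraRate = 0.02,
                         seed = 13)
  chim <- p[p$chimeric, ]
  expect_true(all(chim$start1 >= 1000 & chim$end1 <= 1200))
  expect_true(all(chim$start2 >= 8000 & chim$end2 <= 8200))

  # seed determinism
  expect_identical(p, simulateFripPairs(5000, 19000, anchors,
                                        chimeraRate = 0.02, seed = 13))
  expect_error(simulateFripPairs(100, 19000, chimeraRate = 0.1), "anchors")
  expect_error(
    simulateFripPairs(100, 19000,
                      list(list(left = c(10, 20), right = c(500, 600))),
                      chimeraRate = 0.1),
    "narrower")
})

test_that("the realized chimeric fraction stays inside its binomial interval", {
  anchors <- list(list(left = c(1000, 1200), right = c(8000, 8200)))
  p <- simulateFripPairs(100000, 19000, anchors, chimeraRate = 0.02,
                         seed = 17)
  # binomial 99.9% interval around 0.02 at n = 1e5: ~ +/- 0.0015
  expect_lt(abs(mean(p$chimeric) - 0.02), 0.002)
  # and the long-pair classifier sees (essentially) exactly those
  expect_equal(longPairFraction(p), mean(p$chimeric), tolerance = 0.05)
})

test_that("simulated IP/input tracks carry planted domain enrichment and library sizes", {
  sim <- simulateIpInput(5000, seed = 19, ipReads = 30000,
                         inputReads = 20000)
  expect_equal(sum(sim$ip), 30000)
  expect_equal(sum(sim$input), 20000)
  # fold 1 everywhere: all domains near enrichment 1
  q <- domainEnrichment(sim$ip, sim$input,
                        IRanges(c(1, 2501), c(500, 3000),
                                names = c("a", "b")))
  expect_lt(max(abs(q$enrichment - 1)), 0.2)
  expect_identical(sim, simulateIpInput(5000, seed = 19, ipReads = 30000,
                                        inputReads = 20000))
  expect_error(simulateIpInput(1000, ipReads = 0), ">= 1")
})

test_that("simulated DG sets realize the planted shared fraction", {
  # f = 1, jitter 0: every query DG overlaps the reference
  sets <- simulateDgSets(50, 50, sharedFraction = 1, jitter = 0, seed = 23)
  expect_equal(dgOverlapFraction(sets$query, sets$reference), 1)

  # f = 0: overlap stays near the chance level estimated by the shuffle null
  sets0 <- simulateDgSets(60, 60, sharedFraction = 0, seed = 29)
  obs <- dgOverlapFraction(sets0$query, sets0$reference)
  null <- permutationPvalue(sets0$query, sets0$reference, 19000,
                            nShuffles = 200, seed = 31)
  expect_lt(abs(obs - mean(null$shuffled)), 0.1)

  # f = 0.5: planted half plus chance background
  sets5 <- simulateDgSets(100, 100, sharedFraction = 0.5, jitter = 10,
                          seed = 37)
  obs <- dgOverlapFraction(sets5$query, sets5$reference)
  expect_gt(obs, 0.4)
  expect_lt(obs, 0.75)
  expect_equal(sum(sets5$query$shared), 50L)
})

test_that("simulated irCLIP reads recover planted crosslinks and are deterministic", {
  planted <- c(500L, 1500L, 3000L)
  sim <- simulateIrclip(planted, 5000, lambda = 10, noiseRate = 0,
                        seed = 41)
  s1 <- crosslinkSites(sim$rep1, 5000)
  expect_setequal(s1$pos, planted)
  expect_identical(sim, simulateIrclip(planted, 5000, lambda = 10,
                                       noiseRate = 0, seed = 41))
  # noise adds uniform background reads at the requested rate
  simN <- simulateIrclip(planted, 5000, lambda = 50, noiseRate = 0.2,
                         seed = 43)
  frac <- 1 - sum(simN$rep1$start %in% (planted + 1L)) / nrow(simN$rep1)
  expect_lt(abs(frac - 0.2), 0.08)
})

test_that("generated tables satisfy the consuming modules' validators", {
  anchors <- list(list(left = c(2000, 2200), right = c(9000, 9200)))
  p <- simulateFripPairs(500, 19000, anchors, chimeraRate = 0.05, seed = 47)
  expect_silent(validatePairs(p, 19000))
  sets <- simulateDgSets(20, 20, 0.5, seed = 53)
  expect_silent(validateDgs(sets$query, 19000))
  expect_silent(validateDgs(sets$reference, 19000))
  sim <- simulateIrclip(c(100L, 900L), 2000, seed = 59)
  expect_silent(sites <- crosslinkSites(sim$rep1, 2000))
})
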