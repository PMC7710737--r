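test_that("coverage binning averages each window, including a short final window", {
  expect_equal(binCoverage(rep(1, 250), 100), c(1, 1, 1))
  expect_equal(binCoverage(c(rep(0, 100), rep(2, 100)), 100), c(0, 2))
  expect_error(binCoverage(numeric(0)), "empty")

  # arbitrary vector vs per-window arithmetic-mean oracle
  set.seed(5)
  v <- rpois(437, 3)
  got <- binCoverage(v, 50)
  oracle <- vapply(seq(1, 437, by = 50), function(s)
    mean(v[s:min(s + 49, 437)]), numeric(1))
  expect_equal(got, oracle)
})

test_that("profile normalization pins the anchor quantile and preserves shape", {
  # constant profile: every value is the quantile, pinned to 0.1
  p <- normalizeProfile(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_equal(profileValues(p), rep(0.1, 4))

  # quantile + scaling oracle: ratios 1..4, type-7 25th percentile 1.75
  p <- normalizeProfile(c(1, 2, 3, 4), rep(1, 4), pseudocount = 0)
  expect_equal(profileValues(p),
               c(1, 2, 3, 4) * 0.1 / 1.75, tolerance = 1e-12)
  expect_equal(unname(quantile(profileValues(p), 0.25)), 0.1,
               tolerance = 1e-12)

  # zero-input window survives via the pseudocount
  p <- normalizeProfile(c(3, 1, 1, 1), c(0, 1, 1, 1), pseudocount = 1)
  expect_equal(p@values[1] / p@scaleFactor, 4)

  expect_error(normalizeProfile(c(0, 0, 0), c(1, 1, 1)), "degenerate")
  expect_error(normalizeProfile(c(1, 2), c(1, 1, 1)), "equal length")
})

test_that("normalization output is invariant to library-size scaling of the sample", {
  set.seed(9)
  samp <- rpois(190, 20)
  inp <- rpois(190, 15) + 1
  base <- profileValues(normalizeProfile(samp, inp, pseudocount = 0))
  for (c in c(0.01, 3, 250)) {
    scaled <- profileValues(normalizeProfile(samp * c, inp, pseudocount = 0))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("correlation-distance clustering groups identical and separates anti-correlated profiles", {
  a <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(a, a, rev(a))
  rownames(m) <- c("s1", "s2", "s3")
  cl <- clusterProfiles(m, k = 2)
  d <- as.matrix(cl$dist)
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 2, tolerance = 1e-12)
  expect_equal(cl$clusters[["s1"]], cl$clusters[["s2"]])
  expect_false(cl$clusters[["s1"]] == cl$clusters[["s3"]])

  # planted partition: two duplicated groups of 3 recovered at k = 2
  set.seed(13)
  g1 <- rpois(80, 5); g2 <- rpois(80, 5)
  m <- rbind(g1 + rnorm(80, 0, 0.1), g1 + rnorm(80, 0, 0.1),
             g1 + rnorm(80, 0, 0.1), g2 + rnorm(80, 0, 0.1),
             g2 + rnorm(80, 0, 0.1), g2 + rnorm(80, 0, 0.1))
  rownames(m) <- paste0("s", 1:6)
  cl <- clusterProfiles(m, k = 2)
  expect_equal(length(unique(cl$clusters[1:3])), 1L)
  expect_equal(length(unique(cl$clusters[4:6])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[4])

  # constant profile gets maximal distance, with a warning
  mc <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), flat = c(1, 1, 1, 1))
  expect_warning(cl <- clusterProfiles(mc), "constant")
  expect_equal(as.matrix(cl$dist)["a", "flat"], 2)
})

test_that("PCA variance fractions match the covariance eigenvalue oracle", {
  set.seed(17)
  m <- matrix(rnorm(6 * 50), nrow = 6)
  pca <- pcaProfiles(m)
  ev <- eigen(cov(m) * (nrow(m) - 1), symmetric = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  expect_equal(pca$variance_explained, ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-8)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))

  # sign convention: each component's largest-|loading| entry is positive
  for (j in seq_len(ncol(pca$components)))
    expect_gt(pca$components[which.max(abs(pca$components[, j])), j], 0)

  # scores reproduce the centered data in the component basis
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(pca$scores %*% t(pca$components), centered,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("PCA degenerate cases: mirrored rows load one component; identical rows are an error", {
  r <- c(1, 3, 2, 5, 4)
  pca <- pcaProfiles(rbind(r, -r))
  expect_equal(pca$variance_explained[1], 1)
  expect_error(pcaProfiles(rbind(r, r)), "rank 0")
})

test_that("Spearman correlation uses midranks and the t approximation", {
  expect_equal(correlateProfiles(1:5, 1:5)$rho, 1)
  expect_equal(correlateProfiles(1:5, 5:1)$rho, -1)
  res <- correlateProfiles(1:5, c(2, 1, 4, 3, 5))
  # rank-formula oracle: rho = 1 - 6*sum(d^2)/(n(n^2-1)) without ties
  d <- rank(1:5) - rank(c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)
  expect_equal(res$rho, 0.8, tolerance = 1e-12)
  # t-approximation oracle for the two-sided p
  tstat <- res$rho * sqrt(3 / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * pt(tstat, df = 3, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_warning(res <- correlateProfiles(rep(1, 5), 1:5), "constant")
  expect_false(res$defined)
})

test_that("coverage tracks round-trip through bedGraph", {
  cov <- c(rep(0, 10), rep(3, 20), rep(1.5, 5), rep(0, 15))
  f <- tempfile(fileext = ".bedGraph")
  writeCoverageTrack(cov, f)
  back <- readCoverageTrack(f, length(cov))
  expect_equal(back, cov)
})
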