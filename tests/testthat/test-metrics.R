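fx <- fixtureSuite(32)

test_that("mutual-information metric adds the two source MIs in bits", {
  h <- fx$half01 + 0
  # MI(X, X) = H(X); a fair two-level image carries exactly 1 bit
  expect_equal(mutualInfoMetric(h, h, h), 2)

  # four-level uniform source vs constant partner: H(A) = 2 bits, MI(B,U) = 0
  u4 <- fx$uniform4 + 0
  expect_equal(mutualInfoMetric(u4, fx$const128 + 0, u4), 2)

  # a constant fused image shares no information with any source
  r <- randomImage(1, 64, 64)
  expect_equal(mutualInfoMetric(r, 255 - r, matrix(128, 64, 64)), 0)
  expect_error(mutualInfoMetric(h, h[1:8, ], h), "shape")
})

test_that("edge preservation is 1 on the identical triple and ~0 with no edges", {
  a <- makePhantom(1, 64) + 0
  expect_equal(edgePreservationMetric(a, a, a), 1, tolerance = 1e-6)

  flat <- matrix(128, 64, 64)
  expect_lt(edgePreservationMetric(a, a, flat), 0.01)
  # symmetric in the two sources
  b <- makePhantom(2, 64, "mr_like") + 0
  u <- (a + b) / 2
  expect_equal(edgePreservationMetric(a, b, u),
               edgePreservationMetric(b, a, u))
  expect_equal(edgePreservationMetric(flat, flat, flat), 0)
})

test_that("local SSIM behaves at the self, negative and degenerate corners", {
  set.seed(9)
  w <- matrix(runif(64), 8, 8)
  expect_equal(localSSIM(w, w), 1, tolerance = 1e-9)
  expect_lt(localSSIM(w, 1 - w), 0)
  expect_equal(localSSIM(matrix(0.5, 8, 8), matrix(0.5, 8, 8)), 1)
})

test_that("SSIM-based metric scores 1 whenever the fused image is a source", {
  a <- makePhantom(3, 48) + 0
  expect_equal(ssimFusionMetric(a, a, a), 1, tolerance = 1e-6)
  # dissimilar sources take the max branch; fused = A still scores 1
  b <- 255 - a
  expect_equal(ssimFusionMetric(a, b, a), 1, tolerance = 1e-6)
})

test_that("window-based metrics are symmetric in the source order", {
  for (seed in 1:3) {
    a <- randomImage(seed); b <- randomImage(seed + 50)
    u <- (a + b) / 2
    expect_equal(ssimFusionMetric(a, b, u), ssimFusionMetric(b, a, u),
                 tolerance = 1e-12)
    expect_equal(fusionSimilarityMetric(a, b, u),
                 fusionSimilarityMetric(b, a, u), tolerance = 1e-12)
  }
})

test_that("fusion quality index degrades to ~0 for a structureless fusion", {
  a <- makePhantom(4, 48) + 0
  expect_equal(fusionQualityIndex(a, a, a), 1, tolerance = 1e-6)
  expect_lt(abs(fusionQualityIndex(a, a, matrix(128, 48, 48))), 0.05)
})

test_that("fusion similarity metric saturates toward the copied source", {
  a <- makePhantom(5, 48) + 0
  expect_equal(fusionSimilarityMetric(a, a, a), 1, tolerance = 1e-6)
  set.seed(11)
  b <- matrix(sample(0:255, 48 * 48, replace = TRUE) + 0, 48, 48)
  # U = A: covariance ratio drives sim toward 1 in structured windows
  expect_gt(fusionSimilarityMetric(a, b, a), 0.8)
})

test_that("standard deviation follows the N-1 sample formula", {
  expect_equal(stdMetric(matrix(c(0, 255), 2, 1)), sqrt(2 * 127.5^2))
  expect_equal(stdMetric(matrix(77, 5, 5)), 0)
  r <- randomImage(7)
  expect_equal(stdMetric(r), stdMetric(r + 40))  # translation invariance
  # two-pass textbook computation
  expect_equal(stdMetric(r), sqrt(sum((r - mean(r))^2) / (length(r) - 1)))
  expect_error(stdMetric(matrix(5, 1, 1)), "one pixel")
})

test_that("sliding-window metrics match an explicit per-window loop", {
  for (seed in 1:5) {
    a <- randomImage(seed); b <- randomImage(seed + 10)
    u <- mapValues(scmFuse(a, b, FusionConfig(scm = ScmParams(nMax = 5L))))
    expect_equal(ssimFusionMetric(a, b, u), qsOracle(a, b, u),
                 tolerance = 1e-8)
    expect_equal(fusionQualityIndex(a, b, u), qlOracle(a, b, u),
                 tolerance = 1e-8)
    expect_equal(fusionSimilarityMetric(a, b, u), qtOracle(a, b, u),
                 tolerance = 1e-8)
  }
})

test_that("all six metrics are invariant to transposing the triple", {
  a <- makePhantom(6, 48) + 0
  b <- makePhantom(6, 48, "mr_like") + 0
  u <- mapValues(scmFuse(a, b))
  r1 <- metricReport(a, b, u)
  r2 <- metricReport(t(a), t(b), t(u))
  for (s in c("qm", "qe", "qs", "ql", "qt", "std"))
    expect_equal(slot(r1, s), slot(r2, s), tolerance = 1e-9)
})

test_that("metric report bundles the identity case and round-trips as JSON", {
  h <- fx$half01 + 0
  rep <- metricReport(h, h, h)
  expect_equal(rep@qm, 2)
  expect_equal(rep@qe, 1, tolerance = 1e-6)
  expect_equal(rep@qs, 1, tolerance = 1e-6)
  expect_equal(rep@ql, 1, tolerance = 1e-6)
  expect_equal(rep@qt, 1, tolerance = 1e-6)
  expect_equal(rep@std, stdMetric(h))

  path <- withr::local_tempfile(fileext = ".json")
  writeMetricReport(rep, path)
  back <- readMetricReport(path)
  for (s in c("qm", "qe", "qs", "ql", "qt", "std"))
    expect_identical(slot(back, s), slot(rep, s))

  # deterministic across runs
  rep2 <- metricReport(h, h, h)
  expect_identical(as.list(rep), as.list(rep2))
})
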