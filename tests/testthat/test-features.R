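randomPulses <- function(seed, nr = 16, nc = 16, n = 5) {
  set.seed(seed)
  new("PulseSeries",
      pulses = array(sample(0:1, nr * nc * n, replace = TRUE),
                     c(nr, nc, n)))
}

test_that("patch entropy evaluates the binary Shannon formula in bits", {
  # interior 3x3 patch with K ones -> H(K/9)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  m <- matrix(0L, 7, 7)
  m[4, 3:5] <- 1L  # K = 3 around the centre pixel
  ps <- new("PulseSeries", pulses = array(m, c(7, 7, 1)))
  H <- mapValues(patchEntropySeries(ps, 1))
  expect_equal(H[4, 4, 1], h(1 / 3), tolerance = 1e-12)
  expect_equal(h(1 / 3), 0.9182958, tolerance = 1e-7)

  m4 <- matrix(0L, 7, 7)
  m4[4, 3:5] <- 1L; m4[3, 4] <- 1L  # K = 4 of 9
  ps4 <- new("PulseSeries", pulses = array(m4, c(7, 7, 1)))
  H4 <- mapValues(patchEntropySeries(ps4, 1))
  expect_equal(H4[4, 4, 1], h(4 / 9), tolerance = 1e-12)
  expect_equal(h(4 / 9), 0.9910761, tolerance = 1e-7)
  expect_equal(h(4 / 9), h(5 / 9))  # symmetric in P1 <-> P0
})

test_that("homogeneous patches carry zero entropy at every iteration", {
  ones <- new("PulseSeries", pulses = array(1L, c(6, 6, 3)))
  zeros <- new("PulseSeries", pulses = array(0L, c(6, 6, 3)))
  expect_true(all(mapValues(patchEntropySeries(ones, 1)) == 0))
  expect_true(all(mapValues(patchEntropySeries(zeros, 1)) == 0))
})

test_that("windowed entropy equals brute-force patch counting", {
  for (seed in 1:10) {
    ps <- randomPulses(seed)
    expect_equal(mapValues(patchEntropySeries(ps, 1)),
                 entropyOracle(pulseArray(ps), 1), tolerance = 1e-12)
  }
  ps <- randomPulses(42)
  expect_equal(mapValues(patchEntropySeries(ps, 2)),
               entropyOracle(pulseArray(ps), 2), tolerance = 1e-12)
})

test_that("entropy on the 3x3 lattice peaks at occupancy nearest one half", {
  hs <- vapply(0:9, function(k) {
    p1 <- k / 9
    if (p1 %in% c(0, 1)) 0 else -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
  }, numeric(1))
  expect_equal(which.max(hs) - 1, 4)  # K = 4, i.e. P1 = 4/9
  expect_true(all(hs >= 0 & hs <= 1))
})

test_that("entropy similarity is 1 iff the feature fields coincide", {
  ps <- randomPulses(1)
  va <- patchEntropySeries(ps, 1)
  sEn <- entropySimilarity(va, va)
  expect_true(all(mapValues(sEn) == 1))
  expect_identical(sEn@kind, "entropy")

  vb <- patchEntropySeries(randomPulses(2), 1)
  s2 <- entropySimilarity(va, vb)
  expect_true(any(mapValues(s2) < 1))
  # symmetry in the two arguments
  expect_equal(mapValues(s2), mapValues(entropySimilarity(vb, va)))
})

test_that("entropy similarity follows 1 - D/cs1 and honours the default bound", {
  # single differing entry of 1 bit with cs1 = 60
  a <- array(0, c(2, 2, 20)); b <- a; b[1, 1, 1] <- 1
  fa <- new("EntropyFeatureField", values = a)
  fb <- new("EntropyFeatureField", values = b)
  s <- entropySimilarity(fa, fb, cs1 = 60)
  expect_equal(mapValues(s)[1, 1], 1 - 1 / 60)
  # worst case: all 20 entries differ by the full bit
  bw <- array(1, c(2, 2, 20))
  sw <- entropySimilarity(fa, new("EntropyFeatureField", values = bw))
  expect_equal(mapValues(sw)[1, 1], 1 - sqrt(20) / 60)
  expect_gt(min(mapValues(sw)), 0.9254)
  expect_error(entropySimilarity(fa, new("EntropyFeatureField",
                                         values = array(0, c(3, 3, 20)))),
               "shape")
})

test_that("differential excitation is a Weber-scaled Laplacian response", {
  const <- new("FiringMap", times = matrix(7L, 6, 6), nMax = 20L)
  expect_true(all(mapValues(differentialExcitation(const, 1)) == 0))

  # centre T=2 with two neighbours raised by 3 each -> patch response R = 6
  t <- matrix(2L, 5, 5)
  t[2, 3] <- 5L; t[4, 3] <- 5L
  fm <- new("FiringMap", times = t, nMax = 20L)
  xi <- mapValues(differentialExcitation(fm, 1))
  expect_equal(xi[3, 3], atan(6 / 2), tolerance = 1e-12)
  expect_equal(atan(3), 1.2490458, tolerance = 1e-7)

  # positive rescaling leaves xi unchanged wherever the centre is nonzero
  fm2 <- new("FiringMap", times = t * 3L, nMax = 60L)
  xi2 <- mapValues(differentialExcitation(fm2, 1))
  expect_equal(xi2[t > 0], xi[t > 0], tolerance = 1e-12)
  expect_true(all(abs(xi) < pi / 2))
})

test_that("zero-firing centres saturate instead of dividing by zero", {
  t <- matrix(0L, 5, 5); t[3, 2] <- 10L
  fm <- new("FiringMap", times = t, nMax = 20L)
  xi <- mapValues(differentialExcitation(fm, 1))
  expect_true(all(is.finite(xi)))
  expect_gt(xi[3, 3], pi / 2 - 1e-4)  # neighbour drives xi toward pi/2
})

test_that("WLD similarity is 1 - |dxi|/cs2 with the default floor of 0.8", {
  x <- matrix(0.3, 4, 4)
  ea <- new("ExcitationField", values = x)
  expect_true(all(mapValues(wldSimilarity(ea, ea)) == 1))

  eb <- new("ExcitationField", values = x - pi / 2)
  s <- wldSimilarity(ea, eb, cs2 = 5 * pi)
  expect_equal(mapValues(s)[1, 1], 0.9)
  expect_equal(mapValues(s), mapValues(wldSimilarity(eb, ea)))
  # supremum |dxi| -> pi gives the greatest-lower-bound 0.8
  expect_equal(1 - pi / (5 * pi), 0.8)
  expect_error(wldSimilarity(ea, new("ExcitationField",
                                     values = matrix(0, 3, 3))), "shape")
})

test_that("similarity fields from real SCM runs respect the default bounds", {
  for (seed in c(11, 12)) {
    pa <- runSCM(randomStimulus(seed), ScmParams())
    pb <- runSCM(randomStimulus(seed + 100), ScmParams())
    sEn <- mapValues(entropySimilarity(patchEntropySeries(pa, 1),
                                       patchEntropySeries(pb, 1)))
    expect_true(all(sEn >= 1 - sqrt(20) / 60 & sEn <= 1))
    xa <- differentialExcitation(firingMap(pa), 1)
    xb <- differentialExcitation(firingMap(pb), 1)
    sW <- mapValues(wldSimilarity(xa, xb))
    expect_true(all(sW > 0.8 & sW <= 1))
  }
})
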