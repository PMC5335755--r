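bin02 <- function(s) binPeaks(s, 0.2)

test_that("cosine distance reproduces hand-computed values", {
  a <- bin02(spec(c(100.1, 100.3), c(1, 1)))       # bins {500, 501}
  b <- bin02(spec(100.1, 1))                        # bin {500}
  expect_equal(cosineDistance(a, b), 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosineDistance(a, a), 0, tolerance = 1e-12)
  disj <- bin02(spec(c(300.1, 300.5), c(2, 3)))
  expect_equal(cosineDistance(a, disj), 1)          # no shared bin
  expect_true(is.na(cosineDistance(a, bin02(spec(numeric())))))
  expect_error(cosineDistance(a, binPeaks(spec(100.1), 0.01)), "width")
})

test_that("angle distance counts epsilon-matches with a clamped arccos", {
  mk <- function(mz) binPeaks(spec(mz), 1e-6)       # bins tiny: keep positions
  a <- mk(c(100.00, 200.00, 300.00))
  b <- mk(c(100.03, 310.00))
  expect_equal(angleDistance(a, b, 0.05), acos(1 / sqrt(6)), tolerance = 1e-6)
  expect_equal(angleDistance(a, a, 0.05), 0)
  ## two peaks of a sharing one partner in b: ratio 2/sqrt(2) clamps to 1
  a2 <- mk(c(100.00, 100.04))
  b2 <- mk(100.02)
  expect_equal(angleDistance(a2, b2, 0.05), 0)
  expect_equal(angleDistance(b2, a2, 0.05), acos(1 / sqrt(2)),
               tolerance = 1e-12)                   # asymmetric as defined
})

test_that("parametrized Hausdorff distance reproduces hand-computed values", {
  mk <- function(mz) binPeaks(spec(mz), 1e-6)
  a <- mk(c(100.0, 200.0))
  b <- mk(c(100.1, 200.0))
  expect_equal(hausdorffDistance(a, b, delta = 0.05, kRoot = 50),
               (0.1^(1 / 50) + 0) / 2, tolerance = 1e-6)
  expect_equal(hausdorffDistance(a, a, 0.05, 50), 0)
  ## differences within delta are tolerated entirely
  expect_equal(hausdorffDistance(mk(100.0), mk(100.2), delta = 0.3,
                                 kRoot = 50), 0)
})

test_that("spectrumDistance dispatches on the distance spec", {
  a <- bin02(spec(c(100.1, 250.3), c(4, 2)))
  expect_equal(spectrumDistance(a, a, distanceSpec("cos")), 0)
  expect_equal(spectrumDistance(a, a, distanceSpec("angle")), 0)
  expect_equal(spectrumDistance(a, a, distanceSpec("hausdorff")), 0)
  mk <- function(mz) binPeaks(spec(mz), 1e-6)
  expect_equal(spectrumDistance(mk(c(100, 200)), mk(c(100.1, 200)),
                                distanceSpec("hausdorff", delta = 0.05,
                                             kRoot = 50)),
               0.1^(1 / 50) / 2, tolerance = 1e-6)
})

test_that("all measures agree with brute-force oracles on random pairs", {
  set.seed(2024)
  nPairs <- 1000
  for (i in seq_len(nPairs)) {
    a <- binPeaks(randomSpectrum(), 0.2)
    b <- binPeaks(randomSpectrum(), 0.2)
    expect_equal(cosineDistance(a, b),
                 oracleCosine(binIndex(a), intensity(a),
                              binIndex(b), intensity(b)),
                 tolerance = 1e-10)
    eps <- runif(1, 0, 0.5)
    expect_equal(angleDistance(a, b, eps), oracleAngle(mz(a), mz(b), eps),
                 tolerance = 1e-10)
    delta <- runif(1, 0, 0.5)
    k <- runif(1, 1, 60)
    expect_equal(hausdorffDistance(a, b, delta, k),
                 oracleHausdorff(mz(a), mz(b), delta, k),
                 tolerance = 1e-10)
  }
})

test_that("ranges, symmetry and tolerance monotonicity hold on random pairs", {
  set.seed(77)
  for (i in 1:200) {
    a <- binPeaks(randomSpectrum(), 0.2)
    b <- binPeaks(randomSpectrum(), 0.2)
    dc <- cosineDistance(a, b)
    expect_gte(dc, 0); expect_lte(dc, 1)
    expect_equal(dc, cosineDistance(b, a), tolerance = 1e-12)
    dh <- hausdorffDistance(a, b, 0.05, 50)
    expect_gte(dh, 0)
    expect_equal(dh, hausdorffDistance(b, a, 0.05, 50), tolerance = 1e-12)
    da <- angleDistance(a, b, 0.05)
    expect_gte(da, 0); expect_lte(da, pi / 2)
    ## growing tolerances can only shrink the distances
    expect_lte(angleDistance(a, b, 0.4), da + 1e-12)
    expect_lte(hausdorffDistance(a, b, 0.4, 50), dh + 1e-12)
  }
  ## the angle numerator is directional: measure (and tolerate) asymmetry
  set.seed(78)
  asym <- 0L
  for (i in 1:100) {
    a <- binPeaks(randomSpectrum(p = 6), 0.2)
    b <- binPeaks(randomSpectrum(p = 6), 0.2)
    if (abs(angleDistance(a, b, 0.3) - angleDistance(b, a, 0.3)) > 1e-12)
      asym <- asym + 1L
    ## symmetry does hold whenever both directions find the same match count
    ca <- sum(vapply(mz(a), function(x) any(abs(x - mz(b)) <= 0.3), NA))
    cb <- sum(vapply(mz(b), function(x) any(abs(x - mz(a)) <= 0.3), NA))
    if (ca == cb)
      expect_equal(angleDistance(a, b, 0.3), angleDistance(b, a, 0.3),
                   tolerance = 1e-12)
  }
  expect_lte(asym, 100L)   # asymmetry is possible by design; just recorded
})
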