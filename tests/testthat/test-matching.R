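## run of n same-charge spectra with controllable precursors
uniformRun <- function(n, id = "u", premz = rep(1000, n), charge = rep(2L, n),
                       mzlist = NULL) {
  MsRun(lapply(seq_len(n), function(k)
    Spectrum(mz = if (is.null(mzlist)) c(100, 200 + k) else mzlist[[k]],
             intensity = c(5, 7)[seq_along(if (is.null(mzlist)) c(1, 2)
                                           else mzlist[[k]])],
             scanNumber = k, precursorMz = premz[k],
             precursorCharge = charge[k])), runId = id)
}

test_that("candidate constraints are the rank window, charge and ppm", {
  runJ <- uniformRun(10, "j")
  q <- spec(c(100, 200), premz = 1000, charge = 2L, scan = 5)
  got <- candidateIndices(5, runJ, q, matchParams(ret = 2, prec = 1000))
  expect_equal(got, 3:7)                       # window, 2*ret+1 = 5 ranks
  expect_lte(length(got), 2 * 2 + 1)

  ## ppm: |m_l - m_k| / m_k * 1e6 <= prec
  runP <- uniformRun(2, "p", premz = c(1000.009, 1000.02))
  gotP <- candidateIndices(1, runP, spec(100, premz = 1000.0, charge = 2L),
                           matchParams(ret = 10, prec = 10))
  expect_equal(gotP, 1L)                       # 9 ppm in, 20 ppm out

  ## charge mismatch empties the set; unknown only matches unknown
  runC <- uniformRun(3, "c", charge = rep(3L, 3))
  expect_length(candidateIndices(1, runC, q, matchParams(ret = 10)), 0L)
  runU <- uniformRun(3, "u2", charge = rep(NA_integer_, 3))
  expect_length(candidateIndices(1, runU, q, matchParams(ret = 10)), 0L)
  qU <- spec(100, premz = 1000, charge = NA_integer_)
  expect_equal(candidateIndices(1, runU, qU, matchParams(ret = 10, prec = 100)),
               1:3)
})

test_that("directed distance counts unmatched fractions", {
  ## 4 query spectra: s1 no candidates (charge 3), s2 distance ~1 > cdis,
  ## s3/s4 exact copies in the target -> 2/4 unmatched
  runI <- MsRun(list(
    spec(c(100, 150), scan = 1, premz = 800, charge = 3L),
    spec(c(100.1, 250.1), c(3, 4), scan = 2, premz = 900, charge = 2L),
    spec(c(300.1, 400.1), c(1, 2), scan = 3, premz = 1000, charge = 2L),
    spec(c(500.1, 600.1), c(8, 9), scan = 4, premz = 1100, charge = 2L)),
    runId = "i")
  runJ <- MsRun(list(
    spec(c(700.1, 750.1), c(3, 4), scan = 1, premz = 900, charge = 2L),
    spec(c(300.1, 400.1), c(1, 2), scan = 2, premz = 1000, charge = 2L),
    spec(c(500.1, 600.1), c(8, 9), scan = 3, premz = 1100, charge = 2L),
    spec(c(100, 150), scan = 4, premz = 801, charge = 2L)), runId = "j")
  p <- matchParams(ret = 10, prec = 2000, cdis = 0.3)
  expect_equal(directedRunDistance(runI, runJ, p), 0.5)
  expect_equal(directedRunDistance(runI, runI, p), 0)   # self-match
  expect_error(directedRunDistance(MsRun(list(), "e"), runJ, p), "no spectra")
})

test_that("run distance is the mean of the two directions", {
  set.seed(31)
  a <- randomRun(20, "a")
  b <- randomRun(24, "b")
  p <- matchParams(ret = 5, prec = 1e5, cdis = 0.4)
  expect_equal(runDistance(a, b, p),
               (directedRunDistance(a, b, p) + directedRunDistance(b, a, p)) / 2)
  expect_equal(runDistance(a, a, p), 0)
  ## disjoint charge states: nothing can match in either direction
  b3 <- uniformRun(5, "b3", charge = rep(3L, 5))
  a2 <- uniformRun(5, "a2", charge = rep(2L, 5))
  expect_equal(runDistance(a2, b3, matchParams(ret = 10, prec = 1e5)), 1)
})

test_that("the distance matrix is symmetric with a zero diagonal", {
  set.seed(32)
  runs <- list(randomRun(15, "r1"), randomRun(15, "r2"), randomRun(15, "r3"))
  p <- matchParams(ret = 4, prec = 1e5, cdis = 0.4)
  d <- runDistanceMatrix(runs, p)
  m <- as.matrix(d)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(runDistanceMatrix(list(runs[[1]], runs[[1]]), p), "duplicate")

  ## three copies of one run (distinct ids) give the zero matrix
  same <- lapply(1:3, function(i) MsRun(spectra(runs[[1]]), paste0("c", i)))
  expect_true(all(as.matrix(runDistanceMatrix(same, p)) == 0))
})

test_that("maximal windows reduce to the unconstrained nearest-neighbour oracle", {
  set.seed(33)
  for (rep in 1:4) {
    nI <- sample(10:50, 1)
    nJ <- sample(10:50, 1)
    runI <- randomRun(nI, "i")
    runJ <- randomRun(nJ, "j")
    for (dn in c("cos", "hausdorff")) {
      p <- matchParams(ret = max(nI, nJ), prec = Inf,
                       dist = distanceSpec(dn), cdis = 0.5)
      expect_equal(directedRunDistance(runI, runJ, p),
                   oracleDirectedUnconstrained(runI, runJ, p))
    }
  }
})

test_that("enlarging ret, prec or cdis never increases the directed distance", {
  set.seed(34)
  runI <- randomRun(25, "i")
  runJ <- randomRun(25, "j")
  base <- matchParams(ret = 3, prec = 20000, cdis = 0.3)
  d0 <- directedRunDistance(runI, runJ, base)
  expect_lte(directedRunDistance(runI, runJ, matchParams(ret = 10,
             prec = 20000, cdis = 0.3)), d0)
  expect_lte(directedRunDistance(runI, runJ, matchParams(ret = 3,
             prec = 1e6, cdis = 0.3)), d0)
  expect_lte(directedRunDistance(runI, runJ, matchParams(ret = 3,
             prec = 20000, cdis = 0.8)), d0)
})

test_that("within-species distances fall below between-species distances", {
  ds <- generateDataset(tinyConfig())
  d <- as.matrix(runDistanceMatrix(ds$runs))
  within <- c(d[1, 2], d[3, 4])
  between <- c(d[1, 3], d[1, 4], d[2, 3], d[2, 4])
  expect_true(max(within) < min(between))
})
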