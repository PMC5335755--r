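## toy matrices
sepMatrix <- function() {         # two groups of two, within 0 / between 1
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  m
}

test_that("sums of squares reproduce the closed-form toy decompositions", {
  g <- c("g1", "g1", "g2", "g2")
  res <- permanovaSS(sepMatrix(), g)
  expect_equal(res@ssTotal, 1.0)
  expect_equal(res@ssWithin, 0)
  expect_equal(res@partialR2, 1.0)
  expect_identical(res@pseudoF, Inf)

  allOne <- matrix(1, 4, 4) - diag(4)
  dimnames(allOne) <- list(letters[1:4], letters[1:4])
  res2 <- permanovaSS(allOne, g)
  expect_equal(res2@ssTotal, 1.5)
  expect_equal(res2@ssWithin, 1.0)
  expect_equal(res2@partialR2, 1 / 3)
  expect_equal(res2@pseudoF, (0.5 / 1) / (1.0 / 2))

  zeros <- matrix(0, 4, 4, dimnames = dimnames(allOne))
  expect_equal(permanovaSS(zeros, g)@partialR2, 0)   # degenerate: defined as 0
  expect_error(permanovaSS(allOne, rep("g", 4)), "two groups")
  ## additivity invariant
  expect_equal(res2@ssTotal, res2@ssBetween + res2@ssWithin,
               tolerance = 1e-9)
})

test_that("sums of squares and R2 agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("r", 1:n), paste0("r", 1:n))
    groups <- sample(rep(c("a", "b", "c"), length.out = n))
    res <- permanovaSS(d, groups)
    df <- data.frame(g = groups)
    fit <- vegan::adonis2(as.dist(d) ~ g, data = df, permutations = 2)
    expect_equal(res@ssBetween, fit$SumOfSqs[1], tolerance = 1e-9)
    expect_equal(res@ssTotal, fit$SumOfSqs[nrow(fit)], tolerance = 1e-9)
    expect_equal(res@partialR2, fit$R2[1], tolerance = 1e-9)
    expect_equal(res@pseudoF, fit$F[1], tolerance = 1e-9)
  }
})

test_that("partial R2 is invariant under rescaling the distances", {
  set.seed(10)
  pts <- matrix(rnorm(24), 8)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("r", 1:8), paste0("r", 1:8))
  g <- rep(c("x", "y"), each = 4)
  r2 <- permanovaSS(d, g)@partialR2
  expect_equal(permanovaSS(0.37 * d, g)@partialR2, r2, tolerance = 1e-12)
})

test_that("permutation test matches enumeration and is seed-deterministic", {
  ## label-invariant matrix: every permuted F equals the observed one
  allOne <- matrix(1, 4, 4) - diag(4)
  dimnames(allOne) <- list(letters[1:4], letters[1:4])
  resInv <- permanovaTest(allOne, c("g1", "g1", "g2", "g2"), nPerm = 200,
                          seed = 4)
  expect_equal(resInv@pValue, 1.0)

  ## N = 6, two balanced groups, perfect separation: 2 of the 20 balanced
  ## assignments attain the maximal pseudo-F, so exact p = 0.1
  m <- matrix(1, 6, 6) - diag(6)
  m[1:3, 1:3] <- 0
  m[4:6, 4:6] <- 0
  dimnames(m) <- list(paste0("r", 1:6), paste0("r", 1:6))
  g6 <- rep(c("A", "B"), each = 3)
  ## independent exhaustive oracle over all label assignments
  fOf <- function(lab) {
    r <- permanovaSS(m, lab)
    r@pseudoF
  }
  perms <- combn(6, 3)
  fs <- apply(perms, 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; fOf(lab)
  })
  exactP <- mean(fs >= fOf(g6))
  expect_equal(exactP, 0.1)
  res <- permanovaTest(m, g6, nPerm = 10000, seed = 11)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(res@pValue - exactP), 3 * se + 2e-4)
  ## determinism and the attainable p-value range
  res2 <- permanovaTest(m, g6, nPerm = 10000, seed = 11)
  expect_identical(res@pValue, res2@pValue)
  expect_gte(res@pValue, 1 / (res@nPermutations + 1))
  expect_lte(res@pValue, 1)

  ## with enough runs the p-value reaches the Monte-Carlo floor: 15 runs in
  ## 5 perfectly separated groups, 999 permutations -> p = 1/1000
  big <- matrix(1, 15, 15) - diag(15)
  for (g in 0:4) big[g * 3 + 1:3, g * 3 + 1:3] <- 0
  dimnames(big) <- list(paste0("r", 1:15), paste0("r", 1:15))
  res15 <- permanovaTest(big, rep(paste0("G", 1:5), each = 3), nPerm = 999,
                         seed = 21)
  expect_equal(res15@pValue, 1 / 1000)
  expect_lte(res15@pValue, 0.001)
})

test_that("the factorial designs enumerate 72 + 9 = 81 combinations", {
  g1 <- enumerateGrid(factorialDesign("design1"))
  g2 <- enumerateGrid(factorialDesign("design2"))
  gAll <- enumerateGrid(factorialDesign("both"))
  expect_length(g1, 72L)
  expect_length(g2, 9L)
  expect_length(gAll, 81L)
  ## design 1 levels as specified
  expect_setequal(unique(vapply(g1, function(p) p@topn, 1)), c(20, 50, Inf))
  expect_setequal(unique(vapply(g1, function(p) p@bin, 1)), c(0.01, 0.2))
  expect_setequal(unique(vapply(g1, function(p) p@ret, 1)), c(1000, 3000))
  expect_setequal(unique(vapply(g1, function(p) p@cdis, 1)), c(0.1, 0.3))
  expect_setequal(unique(vapply(g1, function(p) p@dist@name, "")),
                  c("angle", "cos", "hausdorff"))
  expect_true(all(vapply(g1, function(p) p@prec, 1) == 10))
  ## design 2: angle only, higher cutoffs
  expect_true(all(vapply(g2, function(p) p@dist@name, "") == "angle"))
  expect_setequal(unique(vapply(g2, function(p) p@cdis, 1)), c(0.4, 0.5, 0.6))
})

test_that("grid search ranks settings by separation quality", {
  ds <- generateDataset(tinyConfig())
  design <- list(list(topn = Inf, bin = 0.2, ret = 20, prec = 10,
                      dist = list(distanceSpec("cos")),
                      cdis = c(1e-9, 0.3)))   # first setting can match nothing
  tab <- gridSearch(ds$runs, ds$groups, design)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$rank, 1:2)
  expect_equal(tab$cdis[1], 0.3)              # the workable cutoff wins
  expect_gt(tab$partialR2[1], tab$partialR2[2])
  ## ranking is a permutation of the grid
  expect_setequal(tab$cdis, c(1e-9, 0.3))
  single <- gridSearch(ds$runs, ds$groups,
                       list(list(topn = Inf, bin = 0.2, ret = 20, prec = 10,
                                 dist = list(distanceSpec("cos")),
                                 cdis = 0.3)))
  expect_equal(nrow(single), 1L)
})

test_that("method-comparison CV matches hand calculations", {
  lab <- c("A", "B", "C")
  m1 <- matrix(0, 3, 3, dimnames = list(lab, lab))
  m1[upper.tri(m1)] <- c(0.5, 0.4, 0.6)
  m1 <- m1 + t(m1)
  ## absolute differences {0.1, 0.3, 0.2}: sd/mean = 0.1/0.2 = 0.5
  m2 <- m1
  m2[1, 2] <- m2[2, 1] <- m1[1, 2] + 0.1
  m2[1, 3] <- m2[3, 1] <- m1[1, 3] + 0.3
  m2[2, 3] <- m2[3, 2] <- m1[2, 3] - 0.2
  expect_equal(compareMethodsCV(m1, m2), 0.5)
  ## constant shift: differences constant, CV = 0
  expect_equal(compareMethodsCV(m1, m1 + 0.1 - diag(0.1, 3)), 0)
  expect_warning(cv0 <- compareMethodsCV(m1, m1), "undefined")
  expect_true(is.na(cv0))
})
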