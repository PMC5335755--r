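## Independent brute-force oracles. These deliberately share no code with the
## package internals: dense vectors and double loops throughout.

## cosine distance via a dense intensity vector over all bins
oracleCosine <- function(binIdxA, intA, binIdxB, intB) {
  if (length(binIdxA) == 0 || length(binIdxB) == 0) return(NA_real_)
  n <- max(binIdxA, binIdxB) + 1
  va <- numeric(n); vb <- numeric(n)
  va[binIdxA + 1] <- intA
  vb[binIdxB + 1] <- intB
  1 - sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

## angle distance by explicit double loop over peak pairs
oracleAngle <- function(posA, posB, eps) {
  if (length(posA) == 0 || length(posB) == 0) return(NA_real_)
  cnt <- 0
  for (q in seq_along(posA)) {
    found <- FALSE
    for (qs in seq_along(posB))
      if (abs(posA[q] - posB[qs]) <= eps) found <- TRUE
    if (found) cnt <- cnt + 1
  }
  acos(min(max(cnt / sqrt(length(posA) * length(posB)), 0), 1))
}

## parametrized Hausdorff by explicit double loops
oracleHausdorff <- function(posA, posB, delta, k) {
  if (length(posA) == 0 || length(posB) == 0) return(NA_real_)
  h <- function(a, b) {
    total <- 0
    for (q in seq_along(a)) {
      m <- Inf
      for (qs in seq_along(b)) m <- min(m, abs(a[q] - b[qs]))
      total <- total + (if (m > delta) m else 0)^(1 / k)
    }
    total / length(a)
  }
  max(h(posA, posB), h(posB, posA))
}

## unconstrained directed run distance: nearest-neighbour over ALL spectra of
## run j (same charge assumed by the caller), no rank window, no ppm filter
oracleDirectedUnconstrained <- function(runI, runJ, params) {
  bi <- lapply(spectra(runI), function(s)
    binPeaks(selectTopPeaks(s, params@topn), params@bin))
  bj <- lapply(spectra(runJ), function(s)
    binPeaks(selectTopPeaks(s, params@topn), params@bin))
  unmatched <- 0
  for (a in bi) {
    best <- Inf
    for (b in bj) {
      d <- spectrumDistance(a, b, params@dist)
      if (!is.na(d)) best <- min(best, d)
    }
    if (!(best < params@cdis)) unmatched <- unmatched + 1
  }
  unmatched / length(bi)
}

## random peak-list spectrum for oracle comparisons
randomSpectrum <- function(p = sample(2:12, 1), mzMax = 50, scan = 1) {
  Spectrum(mz = sort(runif(p, 1, mzMax)) + cumsum(rep(1e-9, p)),
           intensity = rexp(p, 1 / 100),
           scanNumber = scan, precursorMz = runif(1, 300, 900),
           precursorCharge = 2L)
}

## random run of n spectra, all charge 2, precursors in a tight band so the
## ppm filter can be neutralized by a large prec
randomRun <- function(n, id, mzMax = 80) {
  MsRun(lapply(seq_len(n), function(k) randomSpectrum(mzMax = mzMax, scan = k)),
        runId = id)
}
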