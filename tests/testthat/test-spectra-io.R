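test_that("MGF parsing maps blocks to spectra with sorted peaks", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=t scan=11", "PEPMASS=500.25 1234.5", "CHARGE=2+",
    "100 5", "99 3", "END IONS",
    "BEGIN IONS", "SCANS=12", "PEPMASS=600.10", "CHARGE=3+",
    "RTINSECONDS=45.5", "END IONS"), path)
  run <- readMgf(path, runId = "r")
  expect_s4_class(run, "MsRun")
  expect_equal(nSpectra(run), 2L)
  s1 <- spectra(run)[[1]]
  expect_equal(precursorMz(s1), 500.25)        # first PEPMASS field only
  expect_equal(scanNumber(s1), 11L)            # scan from TITLE
  expect_equal(mz(s1), c(99, 100))             # re-sorted ascending
  expect_equal(intensity(s1), c(3, 5))
  expect_equal(precursorCharge(s1), 2L)
  s2 <- spectra(run)[[2]]
  expect_equal(precursorMz(s2), 600.10)
  expect_equal(precursorCharge(s2), 3L)
  expect_equal(retentionTime(s2), 45.5)
  expect_equal(peakCount(s2), 0L)              # zero-peak block retained
})

test_that("MGF parser flags malformed blocks and absent charge", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), path)
  expect_error(readMgf(path), "block 1.*PEPMASS")
  writeLines(c("BEGIN IONS", "PEPMASS=400", "100 1", "abc", "END IONS"), path)
  expect_error(readMgf(path), "block 1")
  writeLines(c("BEGIN IONS", "PEPMASS=400", "100 1", "END IONS"), path)
  expect_identical(precursorCharge(spectra(readMgf(path))[[1]]),
                   NA_integer_)                # unknown charge preserved
})

test_that("MGF write/read round trip preserves every field", {
  ds <- generateDataset(tinyConfig())
  run <- ds$runs[[1]]
  path <- withr::local_tempfile(fileext = ".mgf")
  writeMgf(run, path)
  back <- readMgf(path, runId = runId(run))
  expect_equal(nSpectra(back), nSpectra(run))
  for (k in seq_len(nSpectra(run))) {
    a <- spectra(run)[[k]]; b <- spectra(back)[[k]]
    expect_identical(scanNumber(b), scanNumber(a))
    expect_identical(precursorCharge(b), precursorCharge(a))
    expect_equal(precursorMz(b), precursorMz(a), tolerance = 1e-9)
    expect_equal(mz(b), mz(a), tolerance = 1e-9)
    expect_equal(intensity(b), intensity(a), tolerance = 1e-9)
  }
})

test_that("mzML reader keeps only MS2 spectra and their metadata", {
  path <- withr::local_tempfile(fileext = ".mzML")
  sp <- list(
    list(msLevel = 1, scan = 1, mz = c(400, 500), int = c(1, 2)),
    list(msLevel = 2, scan = 2, premz = 500.25, charge = 2L, rt = 12.5,
         mz = c(110.1, 220.2, 330.3), int = c(10, 20, 30)),
    list(msLevel = 1, scan = 3, mz = 400, int = 1),
    list(msLevel = 2, scan = 4, premz = 600.1, charge = 3L, rt = 14,
         mz = c(150.5, 250.5), int = c(5, 6)),
    list(msLevel = 2, scan = 5, premz = 700.7, charge = NA, rt = NA,
         mz = 180.8, int = 7))
  writeTestMzML(sp, path)
  run <- readMzML(path, runId = "mz")
  expect_equal(nSpectra(run), 3L)              # MS1 scans filtered out
  s <- spectra(run)[[1]]
  expect_equal(scanNumber(s), 2L)
  expect_equal(precursorMz(s), 500.25)
  expect_equal(precursorCharge(s), 2L)
  expect_equal(retentionTime(s), 12.5)
  expect_equal(mz(s), c(110.1, 220.2, 330.3), tolerance = 1e-12)
  expect_equal(intensity(s), c(10, 20, 30), tolerance = 1e-6)  # 32-bit floats
  expect_identical(precursorCharge(spectra(run)[[3]]), NA_integer_)
})

test_that("mzML reader handles zlib compression and empty files", {
  path <- withr::local_tempfile(fileext = ".mzML")
  writeTestMzML(list(list(msLevel = 2, scan = 9, premz = 420.4, charge = 2L,
                          rt = 1, mz = c(101.5, 202.5), int = c(3, 4))),
                path, zlib = TRUE)
  run <- readMzML(path)
  expect_equal(mz(spectra(run)[[1]]), c(101.5, 202.5), tolerance = 1e-12)
  writeTestMzML(list(list(msLevel = 1, scan = 1, mz = 100, int = 1)), path)
  expect_warning(empty <- readMzML(path), "no MS2")
  expect_equal(nSpectra(empty), 0L)
})

test_that("distance matrix TSV writing round-trips exactly", {
  m <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d <- runDistanceMatrixFromValues(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(d, path)
  lines <- readLines(path)
  expect_length(lines, 3L)                     # header + 2 rows
  back <- readDistanceMatrix(path)
  expect_identical(as.matrix(back), m)
  expect_equal(as.matrix(back)["A", "B"], as.matrix(back)["B", "A"])

  one <- runDistanceMatrixFromValues(matrix(0, 1, dimnames = list("X", "X")))
  writeDistanceMatrix(one, path)
  expect_identical(as.matrix(readDistanceMatrix(path)),
                   matrix(0, 1, dimnames = list("X", "X")))

  bad <- matrix(c(0, 0.1, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(writeDistanceMatrix(bad, path), "symmetric")
})

test_that("a written synthetic dataset re-reads identically", {
  ds <- generateDataset(tinyConfig())
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  for (run in ds$runs) {
    back <- readMgf(file.path(dir, paste0(runId(run), ".mgf")))
    expect_identical(runId(back), runId(run))
    expect_equal(nSpectra(back), nSpectra(run))
    kb <- sample(nSpectra(run), 1)
    expect_equal(mz(spectra(back)[[kb]]), mz(spectra(run)[[kb]]),
                 tolerance = 1e-9)
  }
  ann <- readAnnotations(file.path(dir, "psms.tsv"))
  expect_identical(ann$peptide, ds$annotations$peptide)
})
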