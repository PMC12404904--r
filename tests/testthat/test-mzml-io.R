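# mzML round trips, unit conversion, metadata fidelity, and a cross-check
# of the writer against an independent mzML implementation (mzR).

test_that("write/read round trip preserves scans, arrays and metadata", {
  run <- makeRun(list(
    makeSpectrum(1.00, c(100.5, 249.1888), c(10, 1000), scanId = "scan=1"),
    makeSpectrum(1.01, c(85.0284, 148.0684, 207.1419), c(500, 300, 200),
                 msLevel = 2L, precursorMz = 207.1419, activation = "HCD",
                 nce = 30, scanId = "scan=2"),
    makeSpectrum(1.02, c(85.0284, 207.1419), c(100, 900),
                 msLevel = 2L, precursorMz = 207.1419, activation = "CID",
                 nce = 20, scanId = "scan=3"),
    makeSpectrum(1.03, numeric(), numeric(), scanId = "scan=4")),
    runId = "rt_test", date = "2025-03-01T09:00:00Z")
  f <- tempfile(fileext = ".mzML")
  writeMzML(run, f)
  back <- readMzML(f)

  expect_equal(runId(back), "rt_test")
  expect_equal(acquisitionDate(back), "2025-03-01T09:00:00Z")
  expect_equal(nScans(back), 4L)
  expect_equal(rtMinutes(back), rtMinutes(run), tolerance = 1e-9)
  expect_equal(msLevel(back), msLevel(run))
  for (i in 1:4) {
    expect_equal(peakMz(scans(back)[[i]]), peakMz(scans(run)[[i]]),
                 tolerance = 1e-9)
    expect_equal(peakIntensity(scans(back)[[i]]),
                 peakIntensity(scans(run)[[i]]), tolerance = 1e-9)
    expect_equal(tic(scans(back)[[i]]), sum(peakIntensity(scans(run)[[i]])))
  }
  s2 <- scans(back)[[2]]
  expect_equal(precursorMz(s2), 207.1419)
  expect_equal(activationType(s2), "HCD")
  expect_equal(collisionEnergy(s2), 30)
  expect_equal(s2@isolationWidthMz, 1.5)
  expect_equal(activationType(scans(back)[[3]]), "CID")
  # scans with zero peaks are retained
  expect_length(peakMz(scans(back)[[4]]), 0)
})

test_that("empty runs round-trip and invalid runs fail before writing", {
  f <- tempfile(fileext = ".mzML")
  writeMzML(makeRun(list(), runId = "empty"), f)
  expect_equal(nScans(readMzML(f)), 0L)

  bad <- makeRun(list(makeSpectrum(1.0, c(200, 100), c(1, 1))))
  # constructor sorts; force a violation to exercise the writer guard
  bad@scans[[1]]@mz <- c(200, 100)
  f2 <- tempfile(fileext = ".mzML")
  expect_error(writeMzML(bad, f2), "ascending")
  expect_false(file.exists(f2))
})

test_that("second-unit retention times are converted to minutes", {
  f <- tempfile(fileext = ".mzML")
  run <- makeRun(list(makeSpectrum(4.30, 100, 1, scanId = "scan=1")))
  writeMzML(run, f)
  txt <- readLines(f)
  txt <- gsub('value="4.3" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"',
              'value="258.0" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"',
              txt, fixed = TRUE)
  writeLines(txt, f)
  expect_equal(rtMinutes(readMzML(f)), 4.30, tolerance = 1e-9)
})

test_that("profile-mode advertisement warns but scans still load", {
  f <- tempfile(fileext = ".mzML")
  writeMzML(makeRun(list(makeSpectrum(1, 100, 5, scanId = "scan=1"))), f)
  txt <- readLines(f)
  txt <- gsub('accession="MS:1000127" name="centroid spectrum"',
              'accession="MS:1000128" name="profile spectrum"', txt,
              fixed = TRUE)
  writeLines(txt, f)
  expect_warning(run <- readMzML(f), "profile")
  expect_equal(nScans(run), 1L)
  expect_equal(peakIntensity(scans(run)[[1]]), 5)
})

test_that("non-monotone retention times are reported, not reordered", {
  f <- tempfile(fileext = ".mzML")
  ok <- makeRun(list(makeSpectrum(1, 100, 1, scanId = "scan=1"),
                     makeSpectrum(2, 100, 1, scanId = "scan=2")))
  writeMzML(ok, f)
  txt <- paste(readLines(f), collapse = "\n")
  # bump the first scan start time to fabricate disorder in the file
  txt <- sub('value="1" unitCvRef="UO" unitAccession="UO:0000031"',
             'value="9" unitCvRef="UO" unitAccession="UO:0000031"',
             txt, fixed = TRUE)
  writeLines(txt, f)
  expect_warning(back <- readMzML(f), "not monotone")
  expect_equal(rtMinutes(back), c(9, 2))
})

test_that("missing files and non-mzML content raise errors", {
  expect_error(readMzML(tempfile()), "not found")
  f <- tempfile(fileext = ".mzML")
  writeLines("<foo/>", f)
  expect_error(readMzML(f), "not an mzML")
})

test_that("an independent mzML implementation reads our writer's output", {
  skip_if_not_installed("mzR")
  run <- makeRun(list(
    makeSpectrum(4.2, c(100.1, 249.1888), c(10, 1000), scanId = "scan=1"),
    makeSpectrum(4.21, c(85.0284, 190.1154), c(500, 500), msLevel = 2L,
                 precursorMz = 249.1888, activation = "HCD", nce = 30,
                 scanId = "scan=2")), runId = "xcheck")
  f <- tempfile(fileext = ".mzML")
  writeMzML(run, f)
  h <- NULL
  fh <- mzR::openMSfile(f)
  on.exit(mzR::close(fh))
  h <- mzR::header(fh)
  expect_equal(h$msLevel, c(1L, 2L))
  expect_equal(h$retentionTime, c(4.2, 4.21) * 60, tolerance = 1e-6)
  expect_equal(h$precursorMZ[2], 249.1888, tolerance = 1e-9)
  expect_equal(h$collisionEnergy[2], 30)
  pk <- mzR::peaks(fh, 2)
  expect_equal(pk[, 1], c(85.0284, 190.1154), tolerance = 1e-9)
  expect_equal(pk[, 2], c(500, 500))
})
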