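# Query parsing, canonical rendering, evaluation semantics, and
# equivalence with an independent brute-force filter.

workedQuery <- paste("QUERY scansum(MS1DATA) WHERE MS1MZ=249.1888 AND",
                     "TOLERANCEPPM=10 AND RTMIN=4.13 AND RTMAX=4.46")

test_that("parsing recovers action, source, conditions and tolerance", {
  q <- parseMassQL(workedQuery)
  expect_equal(queryAction(q), "scansum")
  expect_equal(querySource(q), "MS1DATA")
  cond <- queryConditions(q)
  expect_equal(cond$kind, c("MS1MZ", "RTMIN", "RTMAX"))
  expect_equal(cond$value, c(249.1888, 4.13, 4.46))
  expect_equal(queryTolerance(q), list(mode = "ppm", value = 10))
  expect_equal(rtWindow(q), c(4.13, 4.46))

  q2 <- parseMassQL("query SCANINFO(ms2data) where ms2prod = 85.0284")
  expect_equal(queryAction(q2), "scaninfo")
  expect_equal(querySource(q2), "MS2DATA")
  expect_equal(queryConditions(q2)$kind, "MS2PROD")
  expect_equal(queryTolerance(q2)$value, 10) # default tolerance
})

test_that("malformed queries fail with the offending token named", {
  expect_error(parseMassQL("QUERY scansum(MS1DATA) WHERE BOGUS=1"), "BOGUS")
  expect_error(parseMassQL("QUERY scansum(MS1DATA)"), "WHERE")
  expect_error(parseMassQL("QUERY frobnicate(MS1DATA) WHERE MS1MZ=1"),
               "action")
  expect_error(parseMassQL("QUERY scansum(MS1DATA) WHERE MS1MZ=abc"),
               "condition")
  expect_error(parseMassQL("QUERY scansum(MS1DATA) WHERE MS2PROD=85"),
               "MS2DATA")
  expect_error(
    parseMassQL("QUERY scansum(MS1DATA) WHERE MS1MZ=1 AND RTMIN=5 AND RTMAX=2"),
    "RTMIN")
})

test_that("render/parse round-trips, including randomized queries", {
  q <- parseMassQL(workedQuery)
  expect_equal(parseMassQL(renderMassQL(q)), q)
  expect_false(grepl("RTMIN",
                     renderMassQL(parseMassQL(
                       "QUERY scansum(MS1DATA) WHERE MS1MZ=100"))))
  set.seed(11)
  for (i in 1:25) {
    src <- sample(c("MS1DATA", "MS2DATA"), 1)
    kinds <- if (src == "MS1DATA") "MS1MZ"
             else sample(c("MS2PREC", "MS2PROD", "MS2NL"),
                         sample.int(2, 1))
    cond <- data.frame(kind = kinds, value = round(runif(length(kinds),
                                                         50, 900), 4))
    if (runif(1) < 0.5) {
      w <- sort(round(runif(2, 0, 12), 2))
      cond <- rbind(cond, data.frame(kind = c("RTMIN", "RTMAX"), value = w))
    }
    q <- new("MassQLQuery", action = sample(c("scansum", "scaninfo"), 1),
             source = src, conditions = cond,
             toleranceMode = sample(c("ppm", "absolute_mz"), 1),
             toleranceValue = round(runif(1, 0.001, 20), 4))
    expect_equal(parseMassQL(renderMassQL(q)), q)
  }
})

test_that("evaluation matches scans only inside the window and tolerance", {
  run <- gaussianRun()
  q <- parseMassQL(workedQuery)
  res <- evaluateQuery(run, q)
  expect_true(all(res$rt_minutes >= 4.13 & res$rt_minutes <= 4.46))
  expect_true(all(abs(res$ppm_error) <= 10))
  expect_true(all(res$matched_intensity > 0))
  expect_true(all(abs(res$observed_mz - 249.1888) < 1e-9))

  empty <- evaluateQuery(run, parseMassQL(
    "QUERY scansum(MS1DATA) WHERE MS1MZ=500.0 AND TOLERANCEPPM=10"))
  expect_equal(nrow(empty), 0)
})

test_that("multiple in-tolerance peaks in one scan sum their intensities", {
  run <- makeRun(list(
    makeSpectrum(1.0, c(249.1880, 249.1896), c(300, 700), scanId = "scan=1")))
  res <- evaluateQuery(run, parseMassQL(
    "QUERY scansum(MS1DATA) WHERE MS1MZ=249.1888 AND TOLERANCEPPM=10"))
  expect_equal(nrow(res), 1)
  expect_equal(res$matched_intensity, 1000)
  # intensity-weighted mean of the two matched peaks
  expect_equal(res$observed_mz, (249.1880 * 300 + 249.1896 * 700) / 1000)
})

test_that("MS2 condition kinds select by precursor, product and loss", {
  ms2 <- makeSpectrum(2.0, c(85.0284, 148.0684, 207.1419), c(50, 30, 20),
                      msLevel = 2L, precursorMz = 207.1419,
                      activation = "CID", nce = 40, scanId = "scan=1")
  run <- makeRun(list(makeSpectrum(1.9, 207.1419, 100, scanId = "scan=0"),
                      ms2))
  prod <- evaluateQuery(run, parseMassQL(
    "QUERY scaninfo(MS2DATA) WHERE MS2PROD=85.0284 AND TOLERANCEPPM=10"))
  expect_equal(prod$matched_intensity, 50)
  expect_equal(prod$activation, "CID")
  expect_equal(prod$collision_energy, 40)

  prec <- evaluateQuery(run, parseMassQL(
    "QUERY scaninfo(MS2DATA) WHERE MS2PREC=207.1419 AND TOLERANCEPPM=10"))
  expect_equal(nrow(prec), 1)
  expect_equal(prec$matched_intensity, 100) # whole-scan TIC

  nl <- evaluateQuery(run, parseMassQL(
    "QUERY scansum(MS2DATA) WHERE MS2NL=59.0735 AND TOLERANCEPPM=10"))
  expect_equal(nl$matched_intensity, 30) # 207.1419 - 148.0684 = 59.0735
})

test_that("evaluation equals the brute-force oracle on random runs", {
  for (seed in c(101, 202, 303, 404)) {
    run <- randomRun(seed, nScans = 40, maxPeaks = 18, withMs2 = TRUE)
    mzVal <- peakMz(scans(run)[[3]])[1] # guaranteed hittable target
    q <- parseMassQL(sprintf(
      "QUERY scansum(MS1DATA) WHERE MS1MZ=%.6f AND TOLERANCEPPM=500 AND RTMIN=1 AND RTMAX=9",
      mzVal))
    got <- evaluateQuery(run, q)
    ref <- bruteForceEval(run, "MS1DATA", "MS1MZ", mzVal, 500, 1, 9)
    expect_equal(got$scan_id, ref$scan_id)
    expect_equal(got$matched_intensity, ref$matched_intensity)

    q2 <- parseMassQL("QUERY scansum(MS2DATA) WHERE MS2NL=100 AND TOLERANCEPPM=100000")
    got2 <- evaluateQuery(run, q2)
    ref2 <- bruteForceEval(run, "MS2DATA", "MS2NL", 100, 100000)
    expect_equal(got2$scan_id, ref2$scan_id)
    expect_equal(got2$matched_intensity, ref2$matched_intensity)
  }
})

test_that("tolerance tightening and window widening are monotone", {
  run <- randomRun(77, nScans = 30, maxPeaks = 12)
  mzVal <- peakMz(scans(run)[[5]])[2]
  nrows <- function(ppm, lo = 0, hi = 12) {
    nrow(evaluateQuery(run, parseMassQL(sprintf(
      "QUERY scansum(MS1DATA) WHERE MS1MZ=%.6f AND TOLERANCEPPM=%g AND RTMIN=%g AND RTMAX=%g",
      mzVal, ppm, lo, hi))))
  }
  counts <- vapply(c(1, 10, 100, 1000, 10000), nrows, numeric(1))
  expect_true(all(diff(counts) >= 0)) # widening tolerance never drops rows
  wins <- rbind(c(4, 6), c(3, 7), c(1, 9), c(0, 12))
  wcounts <- vapply(seq_len(nrow(wins)), function(i)
    nrows(10000, wins[i, 1], wins[i, 2]), numeric(1))
  expect_true(all(diff(wcounts) >= 0)) # widening the RT window
})

test_that("result is invariant to scan storage order", {
  run <- randomRun(55, nScans = 20, maxPeaks = 10)
  mzVal <- peakMz(scans(run)[[2]])[1]
  q <- parseMassQL(sprintf(
    "QUERY scansum(MS1DATA) WHERE MS1MZ=%.6f AND TOLERANCEPPM=5000", mzVal))
  shuffled <- run
  set.seed(1)
  shuffled@scans <- sample(run@scans)
  got <- evaluateQuery(run, q)
  got2 <- evaluateQuery(shuffled, q)
  expect_equal(got$scan_id, got2$scan_id)
  expect_equal(got$matched_intensity, got2$matched_intensity)
})
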