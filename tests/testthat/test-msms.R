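# MS/MS consistency: scan selection by precursor, TIC normalization, and
# aggregation by activation type x collision energy.

test_that("MS2 scans are selected by precursor tolerance and RT window", {
  fx <- defaultSstFixture(seed = 5, ms1Interval = 0.1, dda = TRUE)
  run <- synthDdaRun(fx$spec, runId = "dda1")
  acetyl <- fx$panel[1, ]
  sel <- selectMs2Scans(run, acetyl$precursor_mz, tolerancePpm(10))
  expect_gt(length(sel), 0)
  expect_true(all(vapply(sel, msLevel, integer(1)) == 2L))
  expect_true(all(abs(vapply(sel, precursorMz, numeric(1)) -
                        acetyl$precursor_mz) < 1e-9))
  # 12 MS2 scans (2 activations x 6 NCEs) per in-window MS1 survey scan
  nMs1InWindow <- sum(msLevel(run) == 1L &
                        rtMinutes(run) >= acetyl$rt_min &
                        rtMinutes(run) <= acetyl$rt_max)
  expect_equal(length(sel), 12 * nMs1InWindow)
  # an RT window further restricts the selection (boundaries inclusive)
  selWin <- selectMs2Scans(run, acetyl$precursor_mz, tolerancePpm(10),
                           rtWindow = c(acetyl$rt_min, acetyl$rt_max))
  expect_lte(length(selWin), length(sel))
  expect_true(all(vapply(selWin, rtMinutes, numeric(1)) <= acetyl$rt_max))
  # tightening the tolerance to exclude the precursor empties the selection
  expect_length(selectMs2Scans(run, acetyl$precursor_mz + 0.01,
                               tolerancePpm(1)), 0)
})

test_that("normalized product intensity is the matched TIC fraction", {
  scan <- makeSpectrum(2.0, c(85.0284, 148.0684), c(50, 50), msLevel = 2L,
                       precursorMz = 207.1419, activation = "HCD", nce = 30)
  expect_equal(normalizedProductIntensity(scan, 85.0284), 0.5)
  expect_equal(normalizedProductIntensity(scan, 400.0), 0.0)
  scan2 <- makeSpectrum(2.0, c(85.0284, 148.0684), c(80, 20), msLevel = 2L,
                        precursorMz = 207.1419)
  # 207.1419 - 148.0684 = 59.0735: the trimethylamine loss peak
  expect_equal(normalizedProductIntensity(scan2, 59.0735,
                                          type = "neutral_loss"), 0.2)
  zero <- makeSpectrum(2.0, 100, 0, msLevel = 2L, precursorMz = 207.1419)
  expect_warning(v <- normalizedProductIntensity(zero, 100), "zero-TIC")
  expect_true(is.na(v))
})

test_that("fractions over a complete disjoint partition sum to one", {
  scan <- makeSpectrum(1, c(85.0284, 148.0684, 207.1419), c(30, 20, 50),
                       msLevel = 2L, precursorMz = 207.1419)
  parts <- vapply(c(85.0284, 148.0684, 207.1419),
                  function(t) normalizedProductIntensity(scan, t),
                  numeric(1))
  expect_true(all(parts >= 0 & parts <= 1))
  expect_equal(sum(parts), 1)
})

test_that("aggregation recovers generator fractions exactly, noiseless", {
  fx <- defaultSstFixture(seed = 6, ms1Interval = 0.1, dda = TRUE)
  days <- lapply(1:5, function(i)
    synthDdaRun(fx$spec, runId = sprintf("day%02d", i), seed = 600 + i))
  prof <- aggregateProfiles(days, fx$panel)
  expect_true(all(prof$mean_norm_intensity >= 0 &
                    prof$mean_norm_intensity <= 1))
  expect_true(all(prof$sd_norm_intensity == 0, na.rm = TRUE))
  expect_false("unknown" %in% prof$activation)

  # every group mean equals the fragment fraction the generator emitted
  for (i in seq_len(nrow(fx$panel))) {
    a <- fx$spec$analytes[[i]]
    fr <- a$fragments
    p85 <- prof[prof$query_name == a$name & prof$target_type == "product", ]
    for (j in seq_len(nrow(p85))) {
      want <- fr$fraction[fr$activation == p85$activation[j] &
                            fr$nce == p85$nce[j] &
                            abs(fr$product_mz - 85.0284) < 1e-6]
      expect_equal(p85$mean_norm_intensity[j], want, tolerance = 1e-12)
    }
    pnl <- prof[prof$query_name == a$name &
                  prof$target_type == "neutral_loss", ]
    nlMz <- a$precursorMz - monoisotopicMass(fx$panel$nl_formula[i])
    for (j in seq_len(nrow(pnl))) {
      want <- fr$fraction[fr$activation == pnl$activation[j] &
                            fr$nce == pnl$nce[j] &
                            abs(fr$product_mz - nlMz) < 1e-6]
      expect_equal(pnl$mean_norm_intensity[j], want, tolerance = 1e-12)
    }
  }
  # the emulated trends: HCD > CID for the 85.0284 product at every NCE,
  # CID > HCD for the neutral loss above NCE 30
  p85 <- prof[prof$target_type == "product" &
                prof$query_name == fx$panel$name[1], ]
  hcd <- p85[p85$activation == "HCD", ][order(p85$nce[p85$activation == "HCD"]), ]
  cid <- p85[p85$activation == "CID", ][order(p85$nce[p85$activation == "CID"]), ]
  expect_true(all(hcd$mean_norm_intensity > cid$mean_norm_intensity))
  expect_true(all(diff(hcd$mean_norm_intensity) > 0)) # monotone in NCE
})

test_that("aggregation is invariant to run order and file splitting", {
  fx <- defaultSstFixture(seed = 8, ms1Interval = 0.1, dda = TRUE)
  r1 <- synthDdaRun(fx$spec, runId = "a", seed = 81)
  r2 <- synthDdaRun(fx$spec, runId = "b", seed = 82)
  p12 <- aggregateProfiles(list(r1, r2), fx$panel)
  p21 <- aggregateProfiles(list(r2, r1), fx$panel)
  expect_equal(p12, p21)

  # splitting one run's scans across two files changes nothing
  half <- nScans(r1) %/% 2
  rA <- makeRun(scans(r1)[seq_len(half)], runId = "a1")
  rB <- makeRun(scans(r1)[(half + 1):nScans(r1)], runId = "a2")
  pSplit <- aggregateProfiles(list(rA, rB, r2), fx$panel)
  expect_equal(pSplit, p12)
})

test_that("scans with unknown activation metadata group separately", {
  s1 <- makeSpectrum(1, c(85.0284, 207.1419), c(40, 60), msLevel = 2L,
                     precursorMz = 207.1419, activation = "HCD", nce = 30)
  s2 <- makeSpectrum(1.1, c(85.0284, 207.1419), c(10, 90), msLevel = 2L,
                     precursorMz = 207.1419, activation = "unknown")
  run <- makeRun(list(s1, s2))
  panel <- data.frame(name = "acetyl", precursor_mz = 207.1419,
                      product_mz = 85.0284)
  prof <- aggregateProfiles(run, panel)
  expect_setequal(prof$activation, c("HCD", "unknown"))
  expect_equal(prof$mean_norm_intensity[prof$activation == "unknown"], 0.1)
})
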