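# Shared fixture builders and the independent brute-force query oracle.

makeSpectrum <- function(rt, mz, intensity, msLevel = 1L, precursorMz = NA,
                         activation = "unknown", nce = NA, scanId = NULL) {
  o <- order(mz)
  new("MsSpectrum",
      scanId = if (is.null(scanId)) sprintf("scan=rt%.4f", rt) else scanId,
      msLevel = as.integer(msLevel), rtMinutes = rt,
      mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
      precursorMz = as.numeric(precursorMz),
      isolationWidthMz = if (msLevel >= 2) 1.5 else NA_real_,
      activation = activation, collisionEnergy = as.numeric(nce))
}

makeRun <- function(scans, runId = "testrun", date = NA_character_) {
  new("MsRun", runId = runId, acquisitionDate = date, scans = scans)
}

# A small MS1 run with one Gaussian analyte, built directly (no generator).
gaussianRun <- function(mzVal = 249.1888, apex = 4.3, sigma = 0.05,
                        amp = 1e6, from = 4.0, to = 4.6, by = 0.01,
                        runId = "gauss") {
  ts <- seq(from, to, by = by)
  makeRun(lapply(seq_along(ts), function(i) {
    y <- amp * exp(-(ts[i] - apex)^2 / (2 * sigma^2))
    makeSpectrum(ts[i], mzVal, y, scanId = sprintf("scan=%d", i))
  }), runId = runId)
}

# Random small runs for oracle-equivalence checks.
randomRun <- function(seed, nScans = 30, maxPeaks = 15, withMs2 = FALSE) {
  set.seed(seed)
  ts <- sort(runif(nScans, 0, 10))
  makeRun(lapply(seq_len(nScans), function(i) {
    isMs2 <- withMs2 && i %% 3 == 0
    np <- sample.int(maxPeaks, 1)
    mz <- sort(runif(np, 100, 500))
    mz <- mz[!duplicated(round(mz, 6))]
    makeSpectrum(ts[i], mz, runif(length(mz), 1, 1000),
                 msLevel = if (isMs2) 2L else 1L,
                 precursorMz = if (isMs2) runif(1, 200, 400) else NA,
                 activation = if (isMs2) sample(c("HCD", "CID"), 1) else "unknown",
                 nce = if (isMs2) sample(c(10, 20, 30), 1) else NA,
                 scanId = sprintf("scan=%d", i))
  }), runId = paste0("rand", seed))
}

# Independent scan-by-scan, peak-by-peak filter: deliberately naive, kept
# structurally separate from evaluateQuery.
bruteForceEval <- function(run, source, mzKind, mzVal, tolPpm,
                           rtmin = -Inf, rtmax = Inf) {
  out <- data.frame(scan_id = character(), rt_minutes = numeric(),
                    matched_intensity = numeric())
  for (s in scans(run)) {
    lv <- msLevel(s)
    if (source == "MS1DATA" && lv != 1L) next
    if (source == "MS2DATA" && lv < 2L) next
    rt <- rtMinutes(s)
    if (rt < rtmin || rt > rtmax) next
    total <- 0
    for (k in seq_along(peakMz(s))) {
      p <- peakMz(s)[k]
      obs <- if (mzKind == "MS2NL") precursorMz(s) - p else p
      if (mzKind == "MS2NL" && (is.na(obs) || obs <= 0)) next
      if (abs((obs - mzVal) / mzVal * 1e6) <= tolPpm)
        total <- total + peakIntensity(s)[k]
    }
    if (total > 0)
      out <- rbind(out, data.frame(scan_id = s@scanId, rt_minutes = rt,
                                   matched_intensity = total))
  }
  out[order(out$rt_minutes), , drop = FALSE]
}
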