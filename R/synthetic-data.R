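#' @include AllClasses.R mzml-io.R formula-mass.R
NULL

#' Analyte specification for the synthetic-run generator
#'
#' Describes one chromatographic analyte: a Gaussian elution profile of the
#' precursor ion plus, for DDA synthesis, a fragment table giving the
#' fraction of the MS2 total ion current carried by each product ion per
#' (activation, NCE) combination. Fractions for one (activation, NCE) must
#' sum to at most 1; the remainder is assigned to a surviving precursor
#' peak so every synthetic MS2 scan has a constant TIC.
#'
#' @param name analyte name.
#' @param precursorMz precursor m/z.
#' @param apexRt,sigmaRt Gaussian apex (minutes) and width (minutes > 0).
#' @param amplitude apex intensity (> 0).
#' @param rtWindow numeric(2), DDA triggering / query window in minutes.
#' @param fragments \code{NULL} or data.frame with columns
#'   \code{activation}, \code{nce}, \code{product_mz}, \code{fraction}.
#' @return a validated list of class \code{"AnalyteSpec"}.
#' @export
analyteSpec <- function(name, precursorMz, apexRt, sigmaRt, amplitude,
                        rtWindow, fragments = NULL) {
  stopifnot(is.character(name), precursorMz > 0, sigmaRt > 0, amplitude >= 0,
            length(rtWindow) == 2, rtWindow[1] <= rtWindow[2])
  if (!is.null(fragments)) {
    stopifnot(all(c("activation", "nce", "product_mz", "fraction")
                  %in% names(fragments)))
    tot <- tapply(fragments$fraction,
                  paste(fragments$activation, fragments$nce), sum)
    if (any(tot > 1 + 1e-12))
      stop("fragment fractions exceed 1 for: ",
           paste(names(tot)[tot > 1 + 1e-12], collapse = ", "))
    if (any(fragments$fraction < 0)) stop("fragment fractions must be >= 0")
  }
  structure(list(name = name, precursorMz = precursorMz, apexRt = apexRt,
                 sigmaRt = sigmaRt, amplitude = amplitude,
                 rtWindow = as.numeric(rtWindow), fragments = fragments),
            class = "AnalyteSpec")
}

#' Generator specification for synthetic runs
#'
#' @param analytes list of [analyteSpec()] objects.
#' @param ms1Interval MS1 scan spacing in minutes.
#' @param runLength run length in minutes.
#' @param noiseAreaSd log-normal sd of the per-run, per-analyte amplitude
#'   multiplier (0 = noiseless); with sd \eqn{s} the relative standard
#'   deviation of peak area across runs converges to
#'   \eqn{100\sqrt{e^{s^2}-1}} percent.
#' @param mzJitterPpmSd per-peak m/z jitter sd in ppm (0 = exact).
#' @param seed integer seed; identical (spec, seed) gives byte-identical
#'   output.
#' @return a validated list of class \code{"GeneratorSpec"}.
#' @export
generatorSpec <- function(analytes, ms1Interval = 0.01, runLength = 11,
                          noiseAreaSd = 0, mzJitterPpmSd = 0, seed = 1L) {
  stopifnot(length(analytes) >= 1, ms1Interval > 0, runLength > 0,
            noiseAreaSd >= 0, mzJitterPpmSd >= 0)
  for (a in analytes)
    if (!inherits(a, "AnalyteSpec")) stop("analytes must be AnalyteSpec objects")
  structure(list(analytes = analytes, ms1Interval = ms1Interval,
                 runLength = runLength, noiseAreaSd = noiseAreaSd,
                 mzJitterPpmSd = mzJitterPpmSd, seed = as.integer(seed)),
            class = "GeneratorSpec")
}

.ms1Scan <- function(spec, t, scanNum, amps, rng) {
  mzv <- numeric(); inten <- numeric()
  for (k in seq_along(spec$analytes)) {
    a <- spec$analytes[[k]]
    y <- amps[k] * exp(-(t - a$apexRt)^2 / (2 * a$sigmaRt^2))
    if (a$amplitude <= 0 || y < 1e-6 * a$amplitude) next
    mz <- a$precursorMz
    if (spec$mzJitterPpmSd > 0)
      mz <- mz * (1 + rng() * spec$mzJitterPpmSd * 1e-6)
    mzv <- c(mzv, mz); inten <- c(inten, y)
  }
  if (length(mzv)) {
    o <- order(mzv); mzv <- mzv[o]; inten <- inten[o]
    # coinciding m/z from two analytes: intensities are summed
    if (anyDuplicated(mzv)) {
      inten <- as.numeric(tapply(inten, factor(mzv, levels = unique(mzv)), sum))
      mzv <- unique(mzv)
    }
  }
  new("MsSpectrum", scanId = sprintf("scan=%d", scanNum), msLevel = 1L,
      rtMinutes = t, mz = mzv, intensity = inten)
}

.runAmps <- function(spec) {
  vapply(spec$analytes, function(a) {
    m <- if (spec$noiseAreaSd > 0) exp(rnorm(1, 0, spec$noiseAreaSd)) else 1
    a$amplitude * m
  }, numeric(1))
}

#' Synthesize an MS1-only run
#'
#' MS1 scans on a regular grid; each analyte contributes one centroid peak
#' at its precursor m/z with Gaussian intensity
#' \eqn{A e^{-(t-\mu)^2/2\sigma^2}}, dropped below \eqn{10^{-6} A}.
#'
#' @param spec a [generatorSpec()].
#' @param runId run identifier.
#' @param acquisitionDate optional ISO 8601 timestamp.
#' @param seed seed override (defaults to \code{spec$seed}); pass distinct
#'   seeds to obtain replicate noisy runs from one spec.
#' @return an [MsRun-class].
#' @export
synthMs1Run <- function(spec, runId = "synth_ms1", acquisitionDate = NA,
                        seed = spec$seed) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(seed)
  rng <- function() rnorm(1)
  amps <- .runAmps(spec)
  times <- seq(0, spec$runLength, by = spec$ms1Interval)
  scans <- vector("list", length(times))
  for (i in seq_along(times))
    scans[[i]] <- .ms1Scan(spec, times[i], i, amps, rng)
  new("MsRun", runId = runId,
      acquisitionDate = if (is.na(acquisitionDate)) NA_character_
                        else as.character(acquisitionDate),
      scans = scans)
}

.ms2Scans <- function(a, t0, dt, scanNum0, nominalTic) {
  fr <- a$fragments
  keys <- unique(fr[order(match(fr$activation, c("HCD", "CID")), fr$nce),
                    c("activation", "nce")])
  out <- vector("list", nrow(keys))
  for (j in seq_len(nrow(keys))) {
    sel <- fr$activation == keys$activation[j] & fr$nce == keys$nce[j]
    pmz <- fr$product_mz[sel]
    pint <- fr$fraction[sel] * nominalTic
    surv <- nominalTic - sum(pint) # precursor survivor keeps TIC constant
    mzv <- c(pmz, a$precursorMz)
    inten <- c(pint, surv)
    keep <- inten > 0
    mzv <- mzv[keep]; inten <- inten[keep]
    o <- order(mzv)
    out[[j]] <- new("MsSpectrum",
      scanId = sprintf("scan=%d", scanNum0 + j), msLevel = 2L,
      rtMinutes = t0 + j * dt, mz = mzv[o], intensity = inten[o],
      precursorMz = a$precursorMz, isolationWidthMz = 1.5,
      activation = keys$activation[j], collisionEnergy = keys$nce[j])
  }
  out
}

#' Synthesize a DDA run
#'
#' MS1 scans as in [synthMs1Run()]; within each analyte's RT window every
#' MS1 scan is followed by a block of MS2 scans for that analyte, HCD at
#' each NCE ascending then CID at each NCE ascending, mirroring
#' inclusion-list DDA scheduling. Each MS2 scan realizes the analyte's
#' fragment fractions of a constant nominal TIC, with the unassigned
#' fraction on the surviving precursor peak.
#'
#' @inheritParams synthMs1Run
#' @param nominalTic MS2 total ion current (default 1e5).
#' @return an [MsRun-class].
#' @export
synthDdaRun <- function(spec, runId = "synth_dda", acquisitionDate = NA,
                        seed = spec$seed, nominalTic = 1e5) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(seed)
  rng <- function() rnorm(1)
  amps <- .runAmps(spec)
  times <- seq(0, spec$runLength, by = spec$ms1Interval)
  scans <- list()
  num <- 1L
  for (t in times) {
    scans[[length(scans) + 1L]] <- .ms1Scan(spec, t, num, amps, rng)
    num <- num + 1L
    active <- Filter(function(a) !is.null(a$fragments) &&
                       t >= a$rtWindow[1] && t <= a$rtWindow[2],
                     spec$analytes)
    if (!length(active)) next
    nTotal <- sum(vapply(active, function(a)
      nrow(unique(a$fragments[, c("activation", "nce")])), integer(1)))
    dt <- spec$ms1Interval / (nTotal + 1L)
    off <- 0L
    for (a in active) {
      blk <- .ms2Scans(a, t + off * dt, dt, num - 1L, nominalTic)
      scans <- c(scans, blk)
      num <- num + length(blk)
      off <- off + length(blk)
    }
  }
  new("MsRun", runId = runId,
      acquisitionDate = if (is.na(acquisitionDate)) NA_character_
                        else as.character(acquisitionDate),
      scans = scans)
}

# The six-analyte deuterated-acylcarnitine SST panel: molecular formulas,
# nominal elution windows (minutes) and the neutral-loss identity
# (trimethylamine vs its d3 analog, inferred from which product ion each
# standard yields). Precursor m/z values are computed from the formulas,
# never transcribed.
.SST_PANEL <- data.frame(
  name = c("acetylcarnitine_d3", "propionylcarnitine_d3",
           "valerylcarnitine_d3", "octanoylcarnitine_d3",
           "lauroylcarnitine_d3", "oleoylcarnitine_d3"),
  formula = c("C9H14D3NO4", "C10H16D3NO4", "C12H20D3NO4",
              "C15H26D3NO4", "C19H34D3NO4", "C25H44D3NO4"),
  rt_min = c(1.11, 3.28, 4.13, 5.74, 7.44, 9.27),
  rt_max = c(1.44, 3.61, 4.46, 6.07, 7.77, 9.59),
  nl_formula = c("C3H9N", "C3H6D3N", "C3H9N",
                 "C3H6D3N", "C3H6D3N", "C3H6D3N"),
  stringsAsFactors = FALSE
)

# Fragment-fraction trends emulated by the DDA fixture: the common m/z
# 85.0284 product grows with NCE and is stronger under HCD, whereas the
# trimethylamine(-d3) neutral-loss product only becomes prominent under
# CID above NCE 30 and stays near-undetectable under HCD.
.FRAC_85 <- list(HCD = c(0.10, 0.25, 0.40, 0.55, 0.65, 0.75),
                 CID = c(0.05, 0.125, 0.20, 0.275, 0.325, 0.375))
.FRAC_NL <- list(HCD = rep(0.01, 6),
                 CID = c(0.02, 0.05, 0.10, 0.35, 0.45, 0.50))
.NCE_GRID <- c(10, 20, 30, 40, 50, 60)
.FRAG_85_MZ <- 85.0284

.panelFragments <- function(precursorMz, nlFormula) {
  nlProduct <- neutralLossProductMz(precursorMz, nlFormula)
  do.call(rbind, lapply(c("HCD", "CID"), function(act) {
    data.frame(
      activation = act,
      nce = rep(.NCE_GRID, 2),
      product_mz = rep(c(.FRAG_85_MZ, nlProduct), each = length(.NCE_GRID)),
      fraction = c(.FRAC_85[[act]], .FRAC_NL[[act]]))
  }))
}

#' Default six-analyte SST fixture
#'
#' A ready-to-run bundle emulating a six-analyte deuterated-acylcarnitine
#' SST panel at desk scale: a [generatorSpec()] with Gaussian elution peaks
#' centered in each analyte's nominal window, a query table, and a
#' reference table of expected apex retention times for deficiency
#' flagging. Three variants support failure-mode testing:
#' \describe{
#'   \item{default}{apexes at the window midpoints; queries carry the
#'     nominal RT windows.}
#'   \item{reversed}{apex retention times permuted into reverse elution
#'     order (wrong column / wrong method scenario); queries are issued
#'     without RT windows so the displaced peaks remain observable.}
#'   \item{shifted}{late eluters (nominal apex >= 5 min) shifted +0.3 min
#'     (column lot drift scenario); windowless screening queries.}
#' }
#'
#' @param seed integer seed for the generator.
#' @param variant one of \code{"default"}, \code{"reversed"},
#'   \code{"shifted"}.
#' @param ms1Interval MS1 scan spacing in minutes (default 0.01).
#' @param amplitude apex intensity of every analyte.
#' @param sigmaRt Gaussian peak width in minutes.
#' @param noiseAreaSd,mzJitterPpmSd noise parameters, see [generatorSpec()].
#' @param dda if \code{TRUE}, attach the panel fragment tables so
#'   [synthDdaRun()] can emit MS2 scans.
#' @return list with elements \code{spec} ([generatorSpec()]),
#'   \code{queries} (data.frame \code{name}, \code{query}), \code{panel}
#'   (data.frame with precursor, window, product-ion and neutral-loss
#'   columns) and \code{reference} (data.frame \code{query_name},
#'   \code{expected_rt}, \code{rt_min}, \code{rt_max}).
#' @export
defaultSstFixture <- function(seed = 1L, variant = c("default", "reversed",
                                                     "shifted"),
                              ms1Interval = 0.01, amplitude = 1e6,
                              sigmaRt = 0.05, noiseAreaSd = 0,
                              mzJitterPpmSd = 0, dda = FALSE) {
  variant <- match.arg(variant)
  panel <- .SST_PANEL
  panel$precursor_mz <- vapply(panel$formula, adductMz, numeric(1))
  panel$product_mz <- .FRAG_85_MZ
  panel$nl_mass <- vapply(panel$nl_formula, monoisotopicMass, numeric(1))
  nominalApex <- (panel$rt_min + panel$rt_max) / 2
  apex <- switch(variant,
    default = nominalApex,
    reversed = rev(nominalApex),
    shifted = nominalApex + ifelse(nominalApex >= 5, 0.3, 0))

  analytes <- lapply(seq_len(nrow(panel)), function(i) {
    frag <- if (dda) .panelFragments(panel$precursor_mz[i],
                                     panel$nl_formula[i]) else NULL
    win <- if (variant == "default") c(panel$rt_min[i], panel$rt_max[i])
           else apex[i] + c(-1, 1) * (panel$rt_max[i] - panel$rt_min[i]) / 2
    analyteSpec(panel$name[i], panel$precursor_mz[i], apex[i], sigmaRt,
                amplitude, win, frag)
  })
  spec <- generatorSpec(analytes, ms1Interval = ms1Interval,
                        runLength = 11, noiseAreaSd = noiseAreaSd,
                        mzJitterPpmSd = mzJitterPpmSd, seed = seed)

  mkQuery <- function(i) {
    base <- sprintf("QUERY scansum(MS1DATA) WHERE MS1MZ=%.4f AND TOLERANCEPPM=10",
                    panel$precursor_mz[i])
    if (variant == "default")
      base <- sprintf("%s AND RTMIN=%s AND RTMAX=%s", base,
                      .fmtNum(panel$rt_min[i]), .fmtNum(panel$rt_max[i]))
    base
  }
  queries <- data.frame(name = panel$name,
                        query = vapply(seq_len(nrow(panel)), mkQuery,
                                       character(1)),
                        stringsAsFactors = FALSE)
  reference <- data.frame(query_name = panel$name,
                          expected_rt = nominalApex,
                          rt_min = panel$rt_min, rt_max = panel$rt_max,
                          stringsAsFactors = FALSE)
  list(spec = spec, queries = queries, panel = panel, reference = reference,
       variant = variant, trueApexRt = apex, trueArea =
         amplitude * sigmaRt * sqrt(2 * pi))
}

#' Write a fixture bundle to disk
#'
#' Materializes a [defaultSstFixture()] as mzML runs plus the JSON query
#' file, JSON batch configuration and CSV reference table that
#' [runBatch()] and the command-line interface consume.
#'
#' @inheritParams defaultSstFixture
#' @param dir output directory (created if needed).
#' @param nRuns number of replicate runs.
#' @param dda write DDA runs (with MS2 scans) instead of MS1-only runs.
#' @param ... passed on to [defaultSstFixture()].
#' @return list with \code{config} (path to config.json), \code{runs}
#'   (mzML paths), \code{queryFile}, \code{referenceFile} and the
#'   \code{fixture} object.
#' @export
writeSstFixture <- function(dir, seed = 1L, variant = "default", nRuns = 3L,
                            dda = FALSE, ...) {
  fx <- defaultSstFixture(seed = seed, variant = variant, dda = dda, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runPaths <- character(nRuns)
  for (i in seq_len(nRuns)) {
    rid <- sprintf("sst_%s_run%02d", variant, i)
    date <- sprintf("2025-01-%02dT08:00:00Z", i)
    run <- if (dda)
      synthDdaRun(fx$spec, runId = rid, acquisitionDate = date,
                  seed = seed * 1000L + i)
    else
      synthMs1Run(fx$spec, runId = rid, acquisitionDate = date,
                  seed = seed * 1000L + i)
    runPaths[i] <- file.path(dir, paste0(rid, ".mzML"))
    writeMzML(run, runPaths[i])
  }
  queryFile <- file.path(dir, "queries.json")
  jsonlite::write_json(fx$queries, queryFile, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  referenceFile <- file.path(dir, "reference.csv")
  utils::write.csv(fx$reference, referenceFile, row.names = FALSE)
  panelFile <- file.path(dir, "panel.csv")
  utils::write.csv(fx$panel, panelFile, row.names = FALSE)
  config <- file.path(dir, "config.json")
  jsonlite::write_json(list(mzml_directory = dir, query_file = queryFile,
                            output_directory = file.path(dir, "out"),
                            reference_file = referenceFile,
                            min_scans = 3, apex_floor = 0),
                       config, auto_unbox = TRUE, digits = NA)
  list(config = config, runs = runPaths, queryFile = queryFile,
       referenceFile = referenceFile, panelFile = panelFile, fixture = fx)
}
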