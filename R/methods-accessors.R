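#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn MsRun-class run identifier
#' @param object an object
#' @export
setMethod("runId", "MsRun", function(object) object@runId)

#' @describeIn MsRun-class acquisition timestamp (ISO 8601) or \code{NA}
#' @export
setMethod("acquisitionDate", "MsRun", function(object) object@acquisitionDate)

#' @describeIn MsRun-class list of \linkS4class{MsSpectrum} scans
#' @export
setMethod("scans", "MsRun", function(object) object@scans)

#' @describeIn MsRun-class number of scans
#' @export
setMethod("nScans", "MsRun", function(object) length(object@scans))

#' @describeIn MsRun-class retention times (minutes) of all scans
#' @export
setMethod("rtMinutes", "MsRun", function(object)
  vapply(object@scans, function(s) s@rtMinutes, numeric(1)))

#' @describeIn MsRun-class MS levels of all scans
#' @export
setMethod("msLevel", "MsRun", function(object)
  vapply(object@scans, function(s) s@msLevel, integer(1)))

#' @describeIn MsSpectrum-class retention time in minutes
#' @param object an object
#' @export
setMethod("rtMinutes", "MsSpectrum", function(object) object@rtMinutes)

#' @describeIn MsSpectrum-class MS level
#' @export
setMethod("msLevel", "MsSpectrum", function(object) object@msLevel)

#' @describeIn MsSpectrum-class centroid m/z array
#' @export
setMethod("peakMz", "MsSpectrum", function(object) object@mz)

#' @describeIn MsSpectrum-class centroid intensity array
#' @export
setMethod("peakIntensity", "MsSpectrum", function(object) object@intensity)

#' @describeIn MsSpectrum-class precursor m/z (\code{NA} for MS1)
#' @export
setMethod("precursorMz", "MsSpectrum", function(object) object@precursorMz)

#' @describeIn MsSpectrum-class activation type (HCD/CID/other/unknown)
#' @export
setMethod("activationType", "MsSpectrum", function(object) object@activation)

#' @describeIn MsSpectrum-class normalized collision energy or \code{NA}
#' @export
setMethod("collisionEnergy", "MsSpectrum", function(object) object@collisionEnergy)

#' @describeIn MsSpectrum-class total ion current, recomputed from the
#'   intensity array
#' @export
setMethod("tic", "MsSpectrum", function(object) sum(object@intensity))

#' @describeIn MassQLQuery-class result action (scansum/scaninfo)
#' @param object an object
#' @export
setMethod("queryAction", "MassQLQuery", function(object) object@action)

#' @describeIn MassQLQuery-class data source (MS1DATA/MS2DATA)
#' @export
setMethod("querySource", "MassQLQuery", function(object) object@source)

#' @describeIn MassQLQuery-class condition table (kind, value)
#' @export
setMethod("queryConditions", "MassQLQuery", function(object) object@conditions)

#' @describeIn MassQLQuery-class tolerance as \code{list(mode, value)}
#' @export
setMethod("queryTolerance", "MassQLQuery", function(object)
  list(mode = object@toleranceMode, value = object@toleranceValue))

#' @describeIn MassQLQuery-class retention-time window
#'   \code{c(min, max)}; \code{-Inf}/\code{Inf} when unbounded
#' @export
setMethod("rtWindow", "MassQLQuery", function(object) {
  cond <- object@conditions
  lo <- cond$value[cond$kind == "RTMIN"]
  hi <- cond$value[cond$kind == "RTMAX"]
  c(if (length(lo)) lo else -Inf, if (length(hi)) hi else Inf)
})

#' @describeIn Eic-class retention-time grid (minutes)
#' @param object an object
#' @export
setMethod("rtMinutes", "Eic", function(object) object@rt)

#' @describeIn Eic-class zero-filled intensity trace
#' @export
setMethod("peakIntensity", "Eic", function(object) object@intensity)

#' @describeIn ChromPeak-class was a peak found?
#' @param object an object
#' @export
setMethod("peakFound", "ChromPeak", function(object) object@found)

#' @describeIn ChromPeak-class trapezoidal peak area (intensity x minutes)
#' @export
setMethod("peakArea", "ChromPeak", function(object) object@area)

#' @describeIn ChromPeak-class apex retention time (minutes)
#' @export
setMethod("apexRt", "ChromPeak", function(object) object@apexRt)

#' @describeIn ChromPeak-class apex intensity
#' @export
setMethod("apexIntensity", "ChromPeak", function(object) object@apexIntensity)

setMethod("show", "MsSpectrum", function(object) {
  cat(sprintf("MsSpectrum %s: MS%d, RT %.4f min, %d peaks, TIC %.4g\n",
              object@scanId, object@msLevel, object@rtMinutes,
              length(object@mz), sum(object@intensity)))
  if (object@msLevel >= 2L)
    cat(sprintf("  precursor m/z %.4f, %s, NCE %s\n", object@precursorMz,
                object@activation,
                ifelse(is.na(object@collisionEnergy), "NA",
                       format(object@collisionEnergy))))
  invisible(NULL)
})

setMethod("show", "MsRun", function(object) {
  lv <- if (length(object@scans)) msLevel(object) else integer()
  cat(sprintf("MsRun '%s': %d scans (%d MS1, %d MSn)", object@runId,
              length(object@scans), sum(lv == 1L), sum(lv > 1L)))
  if (!is.na(object@acquisitionDate))
    cat(", acquired", object@acquisitionDate)
  cat("\n")
  if (length(object@scans)) {
    rt <- rtMinutes(object)
    cat(sprintf("  RT range %.3f-%.3f min\n", min(rt), max(rt)))
  }
  invisible(NULL)
})

setMethod("show", "MassQLQuery", function(object) {
  cat("MassQLQuery:", renderMassQL(object), "\n")
  invisible(NULL)
})

setMethod("show", "Eic", function(object) {
  cat(sprintf("Eic '%s' on run '%s': %d points", object@queryName,
              object@runId, length(object@rt)))
  if (length(object@rt))
    cat(sprintf(", RT %.3f-%.3f min, max intensity %.4g",
                min(object@rt), max(object@rt), max(object@intensity)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "ChromPeak", function(object) {
  if (object@found)
    cat(sprintf(
      "ChromPeak: apex %.4f min (intensity %.4g), area %.6g intensity*min, bounds [%.4f, %.4f], %d scans\n",
      object@apexRt, object@apexIntensity, object@area, object@rtStart,
      object@rtEnd, object@nScans))
  else cat("ChromPeak: not found\n")
  invisible(NULL)
})
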