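#' MsSpectrum: a single mass spectrum (one scan)
#'
#' Container for one centroided scan: MS level, retention time in minutes,
#' the centroid peak list (ascending m/z with non-negative intensities) and,
#' for fragmentation scans, the precursor and activation metadata.
#'
#' The total ion current is always recomputed from the intensity array; it is
#' never trusted from file metadata.
#'
#' @slot scanId character(1), native scan identifier.
#' @slot msLevel integer(1) >= 1.
#' @slot rtMinutes numeric(1) >= 0, retention time in minutes.
#' @slot mz numeric, strictly ascending centroid m/z values.
#' @slot intensity numeric, non-negative, same length as \code{mz}.
#' @slot precursorMz numeric(1); \code{NA} for MS1 scans, present for MSn.
#' @slot isolationWidthMz numeric(1); isolation window full width, or \code{NA}.
#' @slot activation character(1), one of \code{"HCD"}, \code{"CID"},
#'   \code{"other"}, \code{"unknown"}.
#' @slot collisionEnergy numeric(1), normalized collision energy (NCE,
#'   unitless) or \code{NA}.
#'
#' @seealso [MsRun-class], [readMzML()]
#' @export
setClass("MsSpectrum",
  representation(
    scanId = "character",
    msLevel = "integer",
    rtMinutes = "numeric",
    mz = "numeric",
    intensity = "numeric",
    precursorMz = "numeric",
    isolationWidthMz = "numeric",
    activation = "character",
    collisionEnergy = "numeric"
  ),
  prototype(
    scanId = "scan=1", msLevel = 1L, rtMinutes = 0,
    mz = numeric(), intensity = numeric(),
    precursorMz = NA_real_, isolationWidthMz = NA_real_,
    activation = "unknown", collisionEnergy = NA_real_
  )
)

setValidity("MsSpectrum", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have the same length")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msgs <- c(msgs, "mz array must be strictly ascending")
  if (length(object@intensity) && any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(object@msLevel) != 1 || is.na(object@msLevel) || object@msLevel < 1L)
    msgs <- c(msgs, "msLevel must be a single integer >= 1")
  if (length(object@rtMinutes) != 1 || is.na(object@rtMinutes) || object@rtMinutes < 0)
    msgs <- c(msgs, "rtMinutes must be a single non-negative number")
  if (length(object@msLevel) == 1 && !is.na(object@msLevel)) {
    if (object@msLevel == 1L && !is.na(object@precursorMz))
      msgs <- c(msgs, "MS1 scans must not carry a precursor m/z")
    if (object@msLevel >= 2L && is.na(object@precursorMz))
      msgs <- c(msgs, "MSn scans must carry a precursor m/z")
  }
  if (!object@activation %in% c("HCD", "CID", "other", "unknown"))
    msgs <- c(msgs, "activation must be one of HCD, CID, other, unknown")
  if (length(msgs)) msgs else TRUE
})

#' MsRun: one LC-MS run as an ordered collection of scans
#'
#' @slot runId character(1), usually the file stem; unique within a batch.
#' @slot acquisitionDate character(1), ISO 8601 timestamp or \code{NA}.
#' @slot scans list of [MsSpectrum-class], ordered by non-decreasing
#'   retention time.
#'
#' @seealso [readMzML()], [writeMzML()]
#' @export
setClass("MsRun",
  representation(
    runId = "character",
    acquisitionDate = "character",
    scans = "list"
  ),
  prototype(runId = "run", acquisitionDate = NA_character_, scans = list())
)

setValidity("MsRun", function(object) {
  msgs <- character()
  if (length(object@runId) != 1 || is.na(object@runId) || !nzchar(object@runId))
    msgs <- c(msgs, "runId must be a single non-empty string")
  ok <- vapply(object@scans, is, logical(1), class2 = "MsSpectrum")
  if (!all(ok))
    msgs <- c(msgs, "all scans must be MsSpectrum objects")
  if (all(ok) && length(object@scans) > 1) {
    rt <- vapply(object@scans, function(s) s@rtMinutes, numeric(1))
    if (any(diff(rt) < 0))
      msgs <- c(msgs, "scan retention times must be non-decreasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' MassQLQuery: a parsed mass-spectrometry query
#'
#' The query subset supported covers per-scan filtering on precursor m/z
#' (\code{MS1MZ}, \code{MS2PREC}), product m/z (\code{MS2PROD}), neutral loss
#' (\code{MS2NL}) and retention-time windows (\code{RTMIN}/\code{RTMAX}),
#' with a ppm or absolute m/z tolerance.
#'
#' @slot action character(1), \code{"scansum"} or \code{"scaninfo"}.
#' @slot source character(1), \code{"MS1DATA"} or \code{"MS2DATA"}.
#' @slot conditions data.frame with columns \code{kind} (one of
#'   \code{MS1MZ}, \code{MS2PREC}, \code{MS2PROD}, \code{MS2NL},
#'   \code{RTMIN}, \code{RTMAX}) and \code{value}.
#' @slot toleranceMode character(1), \code{"ppm"} or \code{"absolute_mz"}.
#' @slot toleranceValue numeric(1) > 0.
#'
#' @seealso [parseMassQL()], [evaluateQuery()]
#' @export
setClass("MassQLQuery",
  representation(
    action = "character",
    source = "character",
    conditions = "data.frame",
    toleranceMode = "character",
    toleranceValue = "numeric"
  ),
  prototype(
    action = "scansum", source = "MS1DATA",
    conditions = data.frame(kind = character(), value = numeric()),
    toleranceMode = "ppm", toleranceValue = 10
  )
)

.MZ_KINDS <- c("MS1MZ", "MS2PREC", "MS2PROD", "MS2NL")
.RT_KINDS <- c("RTMIN", "RTMAX")

setValidity("MassQLQuery", function(object) {
  msgs <- character()
  if (!object@action %in% c("scansum", "scaninfo"))
    msgs <- c(msgs, "action must be scansum or scaninfo")
  if (!object@source %in% c("MS1DATA", "MS2DATA"))
    msgs <- c(msgs, "source must be MS1DATA or MS2DATA")
  cond <- object@conditions
  if (!all(c("kind", "value") %in% names(cond)))
    return("conditions must have columns kind and value")
  bad <- setdiff(cond$kind, c(.MZ_KINDS, .RT_KINDS))
  if (length(bad))
    msgs <- c(msgs, paste0("unknown condition kind: ", paste(bad, collapse = ", ")))
  if (object@source == "MS1DATA" && any(cond$kind %in% c("MS2PREC", "MS2PROD", "MS2NL")))
    msgs <- c(msgs, "MS2PREC/MS2PROD/MS2NL conditions require source MS2DATA")
  if (object@source == "MS2DATA" && any(cond$kind == "MS1MZ"))
    msgs <- c(msgs, "MS1MZ conditions require source MS1DATA")
  if (sum(cond$kind == "RTMIN") > 1 || sum(cond$kind == "RTMAX") > 1)
    msgs <- c(msgs, "at most one RTMIN and one RTMAX allowed")
  rmin <- cond$value[cond$kind == "RTMIN"]
  rmax <- cond$value[cond$kind == "RTMAX"]
  if (length(rmin) == 1 && length(rmax) == 1 && rmin > rmax)
    msgs <- c(msgs, "RTMIN must not exceed RTMAX")
  if (any(cond$kind %in% .MZ_KINDS & cond$value <= 0))
    msgs <- c(msgs, "m/z-valued conditions must be positive")
  if (any(cond$kind %in% .RT_KINDS & cond$value < 0))
    msgs <- c(msgs, "retention-time conditions must be non-negative")
  if (!object@toleranceMode %in% c("ppm", "absolute_mz"))
    msgs <- c(msgs, "toleranceMode must be ppm or absolute_mz")
  if (length(object@toleranceValue) != 1 || is.na(object@toleranceValue) ||
      object@toleranceValue <= 0)
    msgs <- c(msgs, "toleranceValue must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Eic: an extracted ion chromatogram
#'
#' Intensity versus retention time for one query applied to one run, on the
#' run's scan grid (restricted to the query's retention-time window),
#' zero-filled where no scan matched.
#'
#' @slot queryName character(1).
#' @slot runId character(1).
#' @slot rt numeric, strictly ascending retention times in minutes.
#' @slot intensity numeric, non-negative, same length as \code{rt}.
#'
#' @seealso [buildEic()], [integratePeak()]
#' @export
setClass("Eic",
  representation(
    queryName = "character",
    runId = "character",
    rt = "numeric",
    intensity = "numeric"
  ),
  prototype(queryName = "", runId = "", rt = numeric(), intensity = numeric())
)

setValidity("Eic", function(object) {
  msgs <- character()
  if (length(object@rt) != length(object@intensity))
    msgs <- c(msgs, "rt and intensity must have the same length")
  if (length(object@rt) > 1 && any(diff(object@rt) <= 0))
    msgs <- c(msgs, "rt must be strictly ascending")
  if (length(object@intensity) && any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ChromPeak: the detected chromatographic peak of an EIC
#'
#' When no peak is found all numeric fields are \code{NA}; not-found is a
#' result, not an error.
#'
#' @slot found logical(1).
#' @slot apexRt numeric(1), minutes.
#' @slot apexIntensity numeric(1).
#' @slot area numeric(1), intensity x minutes (trapezoidal).
#' @slot rtStart,rtEnd numeric(1), integration bounds in minutes.
#' @slot nScans integer(1), points in the integration segment.
#'
#' @seealso [integratePeak()]
#' @export
setClass("ChromPeak",
  representation(
    found = "logical",
    apexRt = "numeric",
    apexIntensity = "numeric",
    area = "numeric",
    rtStart = "numeric",
    rtEnd = "numeric",
    nScans = "integer"
  ),
  prototype(
    found = FALSE, apexRt = NA_real_, apexIntensity = NA_real_,
    area = NA_real_, rtStart = NA_real_, rtEnd = NA_real_, nScans = NA_integer_
  )
)

setValidity("ChromPeak", function(object) {
  if (isTRUE(object@found)) {
    if (is.na(object@apexRt) || is.na(object@area) || is.na(object@rtStart) ||
        is.na(object@rtEnd))
      return("a found peak must have apexRt, area and bounds")
    if (object@rtStart > object@apexRt || object@apexRt > object@rtEnd)
      return("apexRt must lie within [rtStart, rtEnd]")
    if (object@area < 0) return("area must be non-negative")
  }
  TRUE
})
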