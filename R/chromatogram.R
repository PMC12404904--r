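#' @include AllClasses.R AllGenerics.R massql.R
NULL

#' Build an extracted ion chromatogram from query matches
#'
#' The retention-time grid is the run's scan grid at the query's source MS
#' level (for \code{MS1DATA} queries: every MS1 scan RT, regardless of
#' interleaved MS2 scans) restricted to the query's retention-time window
#' (the whole run when no window is stated). Intensity is the query's
#' matched intensity where a match row exists and zero elsewhere, so gaps
#' in the signal are explicit rather than interpolated.
#'
#' @param matches data.frame from [evaluateQuery()] for the same
#'   \code{(run, ast)} pair.
#' @param run an [MsRun-class].
#' @param ast the [MassQLQuery-class] that produced \code{matches}.
#' @param queryName label stored on the EIC.
#' @return an [Eic-class].
#' @export
buildEic <- function(matches, run, ast, queryName = "") {
  stopifnot(is(run, "MsRun"), is(ast, "MassQLQuery"))
  lvl <- msLevel(run)
  gridAll <- rtMinutes(run)[if (ast@source == "MS1DATA") lvl == 1L else lvl >= 2L]
  if (!length(gridAll))
    stop("run '", run@runId, "' has no ", ast@source, " scans")
  win <- rtWindow(ast)
  grid <- gridAll[gridAll >= win[1] & gridAll <= win[2]]
  if (!length(grid))
    stop("no ", ast@source, " scans of run '", run@runId,
         "' fall inside the RT window [", win[1], ", ", win[2],
         "] (this is an empty grid, not merely absent signal)")
  inten <- numeric(length(grid))
  if (nrow(matches)) {
    idx <- match(round(matches$rt_minutes, 9), round(grid, 9))
    keep <- !is.na(idx)
    inten[idx[keep]] <- matches$matched_intensity[keep]
  }
  new("Eic", queryName = queryName, runId = run@runId,
      rt = grid, intensity = inten)
}

#' Detect and integrate the chromatographic peak of an EIC
#'
#' The apex is the global intensity maximum (earliest retention time wins
#' ties). The integration segment is the contiguous run of nonzero points
#' containing the apex, extended by the single zero-valued boundary point
#' on each side where one exists (so an isolated spike between zeros still
#' integrates as a triangle). A peak is found iff the apex intensity
#' exceeds \code{apexFloor} and the segment spans at least \code{minScans}
#' points; the area is the trapezoidal integral of intensity over
#' retention time across the segment, in intensity x minutes. No smoothing
#' and no baseline subtraction are applied.
#'
#' @param eic an [Eic-class].
#' @param minScans minimum number of points in the integration segment
#'   (default 3, i.e. at least one nonzero point flanked by its bounds).
#' @param apexFloor minimum apex intensity, exclusive (default 0).
#' @return a [ChromPeak-class]; not-found is a result, not an error.
#' @examples
#' e <- new("Eic", queryName = "q", runId = "r",
#'          rt = c(1.0, 1.1, 1.2), intensity = c(0, 100, 0))
#' integratePeak(e)  # apex 1.1, area 10 intensity*min
#' @export
integratePeak <- function(eic, minScans = 3L, apexFloor = 0) {
  stopifnot(is(eic, "Eic"))
  validObject(eic)
  y <- eic@intensity; x <- eic@rt
  notFound <- new("ChromPeak", found = FALSE)
  if (!length(y)) return(notFound)
  apex <- which.max(y) # earliest index on ties
  if (!(y[apex] > apexFloor)) return(notFound)
  i0 <- apex
  while (i0 > 1L && y[i0 - 1L] > 0) i0 <- i0 - 1L
  i1 <- apex
  while (i1 < length(y) && y[i1 + 1L] > 0) i1 <- i1 + 1L
  # bounding zero points (baseline anchors) belong to the segment
  if (i0 > 1L) i0 <- i0 - 1L
  if (i1 < length(y)) i1 <- i1 + 1L
  n <- i1 - i0 + 1L
  if (n < minScans) return(notFound)
  seg <- i0:i1
  area <- sum(diff(x[seg]) * (head(y[seg], -1L) + tail(y[seg], -1L)) / 2)
  new("ChromPeak", found = TRUE, apexRt = x[apex], apexIntensity = y[apex],
      area = area, rtStart = x[i0], rtEnd = x[i1], nScans = n)
}
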