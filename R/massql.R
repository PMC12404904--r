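#' @include AllClasses.R AllGenerics.R formula-mass.R
NULL

#' Parse a mass-spectrometry query string
#'
#' Grammar (whitespace-insensitive, keywords case-insensitive):
#' \preformatted{QUERY action(source) WHERE cond [AND cond]...}
#' where \code{action} is \code{scansum} or \code{scaninfo}, \code{source}
#' is \code{MS1DATA} or \code{MS2DATA}, and each condition is
#' \code{KEYWORD=number} with keyword one of \code{MS1MZ}, \code{MS2PREC},
#' \code{MS2PROD}, \code{MS2NL}, \code{RTMIN}, \code{RTMAX},
#' \code{TOLERANCEPPM}, \code{TOLERANCEMZ}. The tolerance defaults to
#' 10 ppm when none is stated. The worked panel query
#' \preformatted{QUERY scansum(MS1DATA) WHERE MS1MZ=249.1888 AND
#'   TOLERANCEPPM=10 AND RTMIN=4.13 AND RTMAX=4.46}
#' extracts the valeryl-carnitine-d3 precursor trace in its elution window.
#'
#' @param text character(1) query string.
#' @return a [MassQLQuery-class]; \code{parseMassQL(renderMassQL(q))}
#'   reproduces \code{q}.
#' @seealso [renderMassQL()], [evaluateQuery()]
#' @export
parseMassQL <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    stop("query must be a single non-empty string")
  m <- regexec(
    "^\\s*QUERY\\s+([A-Za-z]+)\\s*\\(\\s*([A-Za-z0-9]+)\\s*\\)\\s*(?:WHERE\\s*(.*))?$",
    text, ignore.case = TRUE)
  parts <- regmatches(text, m)[[1]]
  if (!length(parts))
    stop("malformed query (expected 'QUERY action(source) WHERE ...'): ", text)
  action <- tolower(parts[2])
  src <- toupper(parts[3])
  if (!action %in% c("scansum", "scaninfo"))
    stop("unknown query action: ", parts[2])
  if (!src %in% c("MS1DATA", "MS2DATA"))
    stop("unknown data source: ", parts[3])
  rest <- parts[4]
  if (is.na(rest) || !nzchar(trimws(rest)))
    stop("missing WHERE clause in query: ", text)

  toks <- strsplit(rest, "(?i)\\s+AND\\s+", perl = TRUE)[[1]]
  kinds <- character(); values <- numeric()
  tolMode <- NULL; tolValue <- NULL
  for (tok in toks) {
    cm <- regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*([-+0-9.eE]+)\\s*$", tok)
    cp <- regmatches(tok, cm)[[1]]
    if (!length(cp)) stop("malformed condition: '", trimws(tok), "'")
    kw <- toupper(cp[2])
    val <- suppressWarnings(as.numeric(cp[3]))
    if (is.na(val)) stop("non-numeric value in condition: '", trimws(tok), "'")
    if (kw %in% c("TOLERANCEPPM", "TOLERANCEMZ")) {
      if (!is.null(tolMode)) stop("multiple tolerance conditions in query")
      if (val <= 0) stop("tolerance must be positive")
      tolMode <- if (kw == "TOLERANCEPPM") "ppm" else "absolute_mz"
      tolValue <- val
    } else if (kw %in% c(.MZ_KINDS, .RT_KINDS)) {
      kinds <- c(kinds, kw); values <- c(values, val)
    } else stop("unknown query keyword: ", kw)
  }
  q <- new("MassQLQuery", action = action, source = src,
           conditions = data.frame(kind = kinds, value = values),
           toleranceMode = if (is.null(tolMode)) "ppm" else tolMode,
           toleranceValue = if (is.null(tolValue)) 10 else tolValue)
  validObject(q)
  q
}

#' Render a query to canonical text
#'
#' Single-line canonical form; \code{parseMassQL(renderMassQL(q))} equals
#' \code{q}. Numeric values are printed with the shortest decimal
#' representation that round-trips the stored double exactly.
#'
#' @param ast a [MassQLQuery-class].
#' @return character(1).
#' @export
renderMassQL <- function(ast) {
  stopifnot(is(ast, "MassQLQuery"))
  cond <- ast@conditions
  parts <- character()
  if (nrow(cond))
    parts <- sprintf("%s=%s", cond$kind, vapply(cond$value, .fmtNum, character(1)))
  tolKw <- if (ast@toleranceMode == "ppm") "TOLERANCEPPM" else "TOLERANCEMZ"
  parts <- c(parts, sprintf("%s=%s", tolKw, .fmtNum(ast@toleranceValue)))
  sprintf("QUERY %s(%s) WHERE %s", ast@action, ast@source,
          paste(parts, collapse = " AND "))
}

#' Evaluate a query against a run
#'
#' A scan matches iff (a) its MS level matches the query source, (b) its
#' retention time lies inside \code{[RTMIN, RTMAX]} (boundaries inclusive)
#' when stated, and (c) the m/z condition is satisfied: \code{MS1MZ} /
#' \code{MS2PROD} require at least one centroid peak within tolerance of
#' the value, \code{MS2PREC} tests the recorded precursor m/z, and
#' \code{MS2NL} requires a peak \code{p} with \code{precursorMz - p} within
#' tolerance of the stated loss. Scans with no qualifying signal are
#' omitted (an empty table is a valid result), so every emitted row
#' implicitly passes the mass-accuracy gate \code{|ppm| <= tolerance}.
#'
#' \code{matched_intensity} sums all qualifying peak intensities in the
#' scan; \code{observed_mz} is their intensity-weighted mean m/z and
#' \code{ppm_error} is computed from it against the query m/z (for neutral
#' losses, against the implied product m/z \code{precursorMz - loss}).
#'
#' @param run an [MsRun-class].
#' @param ast a [MassQLQuery-class].
#' @return data.frame with columns \code{run_id}, \code{scan_id},
#'   \code{rt_minutes}, \code{matched_intensity}, \code{observed_mz},
#'   \code{ppm_error}, ordered by retention time; for \code{scaninfo}
#'   queries additionally \code{ms_level}, \code{precursor_mz},
#'   \code{activation}, \code{collision_energy}.
#' @export
evaluateQuery <- function(run, ast) {
  stopifnot(is(run, "MsRun"), is(ast, "MassQLQuery"))
  validObject(ast)
  tol <- list(mode = ast@toleranceMode, value = ast@toleranceValue)
  win <- rtWindow(ast)
  cond <- ast@conditions
  mzCond <- cond[cond$kind %in% .MZ_KINDS, , drop = FALSE]

  rows <- list()
  for (s in run@scans) {
    if (ast@source == "MS1DATA" && s@msLevel != 1L) next
    if (ast@source == "MS2DATA" && s@msLevel < 2L) next
    if (s@rtMinutes < win[1] || s@rtMinutes > win[2]) next

    matchedIdx <- NULL; refPeakMz <- NA_real_; refPrecMz <- NA_real_
    ok <- TRUE
    for (k in seq_len(nrow(mzCond))) {
      kind <- mzCond$kind[k]; val <- mzCond$value[k]
      if (kind == "MS2PREC") {
        if (is.na(s@precursorMz) || !withinTolerance(s@precursorMz, val, tol)) {
          ok <- FALSE; break
        }
        if (is.na(refPrecMz)) refPrecMz <- val
      } else if (kind == "MS2NL") {
        if (is.na(s@precursorMz)) { ok <- FALSE; break }
        losses <- s@precursorMz - s@mz
        hit <- which(losses > 0 & withinTolerance(losses, val, tol))
        if (!length(hit)) { ok <- FALSE; break }
        matchedIdx <- union(matchedIdx, hit)
        if (is.na(refPeakMz)) refPeakMz <- s@precursorMz - val
      } else { # MS1MZ or MS2PROD: direct centroid match
        hit <- which(withinTolerance(s@mz, val, tol))
        if (!length(hit)) { ok <- FALSE; break }
        matchedIdx <- union(matchedIdx, hit)
        if (is.na(refPeakMz)) refPeakMz <- val
      }
    }
    if (!ok) next
    refMz <- if (!is.na(refPeakMz)) refPeakMz else refPrecMz

    if (length(matchedIdx)) {
      inten <- s@intensity[matchedIdx]
      if (sum(inten) <= 0) next
      obs <- sum(s@mz[matchedIdx] * inten) / sum(inten)
      mi <- sum(inten)
    } else if (nrow(mzCond)) { # precursor-only condition (MS2PREC)
      obs <- s@precursorMz
      mi <- sum(s@intensity)
      if (mi <= 0) next
    } else { # no m/z condition: whole-scan TIC
      mi <- sum(s@intensity)
      if (mi <= 0) next
      obs <- NA_real_; refMz <- NA_real_
    }
    ppm <- if (!is.na(refMz) && !is.na(obs)) ppmError(obs, refMz) else NA_real_

    row <- data.frame(run_id = run@runId, scan_id = s@scanId,
                      rt_minutes = s@rtMinutes, matched_intensity = mi,
                      observed_mz = obs, ppm_error = ppm)
    if (ast@action == "scaninfo") {
      row$ms_level <- s@msLevel
      row$precursor_mz <- s@precursorMz
      row$activation <- s@activation
      row$collision_energy <- s@collisionEnergy
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else {
           out0 <- data.frame(run_id = character(), scan_id = character(),
                              rt_minutes = numeric(),
                              matched_intensity = numeric(),
                              observed_mz = numeric(), ppm_error = numeric())
           if (ast@action == "scaninfo") {
             out0$ms_level <- integer(); out0$precursor_mz <- numeric()
             out0$activation <- character(); out0$collision_energy <- numeric()
           }
           out0
         }
  out <- out[order(out$rt_minutes), , drop = FALSE]
  rownames(out) <- NULL
  out
}
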