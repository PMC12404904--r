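#' @include AllClasses.R massql.R chromatogram.R mzml-io.R
NULL

#' Load a named-query set
#'
#' Accepts either a JSON array of objects or an xlsx sheet (first sheet,
#' read with \pkg{readxl}). Two layouts are recognized: full query strings
#' (columns/keys \code{name}, \code{query}) or per-argument columns
#' (\code{name}, \code{mz}, optional \code{tolerance_ppm}, \code{rt_min},
#' \code{rt_max}), from which MS1 scansum queries are composed. Every
#' query is parsed eagerly so malformed entries fail at load time with
#' their position; duplicate names are rejected.
#'
#' @param path path to a \code{.json} or \code{.xlsx} query file.
#' @return data.frame with columns \code{name} and \code{query}; an empty
#'   set triggers a warning.
#' @export
loadQueryset <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0) data.frame(name = character(), query = character())
    else as.data.frame(x, stringsAsFactors = FALSE)
  } else if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx query files requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = 1))
  } else stop("unsupported query file type: .", ext, " (use .json or .xlsx)")

  if (!nrow(df)) {
    warning("query file ", path, " contains no queries")
    return(data.frame(name = character(), query = character(),
                      stringsAsFactors = FALSE))
  }
  if (!"name" %in% names(df)) stop("query file must have a 'name' column")
  if (!"query" %in% names(df)) {
    if (!"mz" %in% names(df))
      stop("query file must have either a 'query' or an 'mz' column")
    # per-argument layout: compose MS1 scansum queries
    df$query <- vapply(seq_len(nrow(df)), function(i) {
      q <- sprintf("QUERY scansum(MS1DATA) WHERE MS1MZ=%s", .fmtNum(df$mz[i]))
      tp <- if ("tolerance_ppm" %in% names(df)) df$tolerance_ppm[i] else NA
      q <- sprintf("%s AND TOLERANCEPPM=%s", q,
                   .fmtNum(if (is.na(tp)) 10 else tp))
      if ("rt_min" %in% names(df) && !is.na(df$rt_min[i]))
        q <- sprintf("%s AND RTMIN=%s", q, .fmtNum(df$rt_min[i]))
      if ("rt_max" %in% names(df) && !is.na(df$rt_max[i]))
        q <- sprintf("%s AND RTMAX=%s", q, .fmtNum(df$rt_max[i]))
      q
    }, character(1))
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop("duplicate query name(s): ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    tryCatch(parseMassQL(df$query[i]), error = function(e)
      stop("query ", i, " ('", df$name[i], "') failed to parse: ",
           conditionMessage(e), call. = FALSE))
  }
  df[, unique(c("name", "query", intersect(
    c("product_mz", "neutral_loss_formula", "rt_min", "rt_max"),
    names(df)))), drop = FALSE]
}

#' Load a batch configuration
#'
#' @param path path to a JSON configuration file with keys
#'   \code{mzml_directory}, \code{query_file}, \code{output_directory},
#'   and optional \code{reference_file}, \code{min_scans},
#'   \code{apex_floor}, \code{rt_margin}.
#' @return the configuration as a list with defaults filled in.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("mzml_directory", "query_file"))
    if (is.null(cfg[[k]])) stop("config is missing required key '", k, "'")
  if (is.null(cfg$output_directory))
    cfg$output_directory <- file.path(cfg$mzml_directory, "out")
  if (is.null(cfg$min_scans)) cfg$min_scans <- 3L
  if (is.null(cfg$apex_floor)) cfg$apex_floor <- 0
  if (is.null(cfg$rt_margin)) cfg$rt_margin <- 0.1
  cfg
}

.listRuns <- function(dir) {
  paths <- list.files(dir, pattern = "\\.mzML(\\.gz)?$", full.names = TRUE,
                      ignore.case = TRUE)
  sort(paths)
}

#' Apply every query to every run
#'
#' The batch pipeline: each run is read once; for every (run, query) pair
#' the query is evaluated, the EIC built and its peak integrated, yielding
#' exactly one record per pair. Runs are ordered by acquisition date when
#' the files carry one, else by filename; the position is recorded in
#' \code{run_index}. A failure on one file is caught, logged into the
#' \code{"errors"} attribute of the result and does not abort the batch.
#'
#' @param config a configuration list (see [loadConfig()]) or the path to
#'   a JSON configuration file.
#' @return data.frame of per-(run x query) records with columns
#'   \code{run_id}, \code{run_index}, \code{query_name}, \code{found},
#'   \code{apex_rt}, \code{apex_intensity}, \code{area},
#'   \code{observed_mz}, \code{ppm_error}; attributes \code{"errors"}
#'   (data.frame of per-file failures) and \code{"eics"} (list of
#'   [Eic-class] keyed \code{runId|queryName}, for plotting).
#' @export
runBatch <- function(config) {
  if (is.character(config)) config <- loadConfig(config)
  queries <- loadQueryset(config$query_file)
  if (!nrow(queries)) stop("no queries to run")
  paths <- .listRuns(config$mzml_directory)
  if (!length(paths)) stop("no mzML runs found in ", config$mzml_directory)
  asts <- lapply(queries$query, parseMassQL)
  names(asts) <- queries$name

  runs <- list(); errors <- data.frame(path = character(), error = character())
  for (p in paths) {
    r <- tryCatch(readMzML(p), error = function(e) e)
    if (inherits(r, "error")) {
      warning("failed to read ", p, ": ", conditionMessage(r))
      errors <- rbind(errors, data.frame(path = p,
                                         error = conditionMessage(r)))
    } else runs[[length(runs) + 1L]] <- r
  }
  if (!length(runs)) stop("no readable runs in ", config$mzml_directory)
  dates <- vapply(runs, acquisitionDate, character(1))
  ord <- if (all(!is.na(dates))) order(dates, vapply(runs, runId, character(1)))
         else order(vapply(runs, runId, character(1)))
  runs <- runs[ord]

  minScans <- as.integer(config$min_scans %||% 3L)
  apexFloor <- config$apex_floor %||% 0
  rows <- vector("list", length(runs) * nrow(queries))
  eics <- list()
  k <- 0L
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    for (qn in queries$name) {
      ast <- asts[[qn]]
      rec <- tryCatch({
        m <- evaluateQuery(run, ast)
        eic <- buildEic(m, run, ast, queryName = qn)
        pk <- integratePeak(eic, minScans = minScans, apexFloor = apexFloor)
        eics[[paste(runId(run), qn, sep = "|")]] <- eic
        obs <- ppm <- NA_real_
        if (pk@found && nrow(m)) {
          j <- which.min(abs(m$rt_minutes - pk@apexRt))
          obs <- m$observed_mz[j]; ppm <- m$ppm_error[j]
        }
        data.frame(run_id = runId(run), run_index = i, query_name = qn,
                   found = pk@found, apex_rt = pk@apexRt,
                   apex_intensity = pk@apexIntensity, area = pk@area,
                   observed_mz = obs, ppm_error = ppm)
      }, error = function(e) {
        warning("query '", qn, "' failed on run '", runId(run), "': ",
                conditionMessage(e))
        errors <<- rbind(errors, data.frame(
          path = runId(run), error = paste0(qn, ": ", conditionMessage(e))))
        data.frame(run_id = runId(run), run_index = i, query_name = qn,
                   found = FALSE, apex_rt = NA_real_,
                   apex_intensity = NA_real_, area = NA_real_,
                   observed_mz = NA_real_, ppm_error = NA_real_)
      })
      k <- k + 1L
      rows[[k]] <- rec
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  attr(out, "eics") <- eics
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-run statistics per query
#'
#' Per-query longitudinal summary over found records only: counts, mean,
#' sample (n-1) standard deviation and relative standard deviation
#' (\code{RSD = sd/mean * 100}, defined only for \code{n_found >= 2} and
#' positive mean) of apex retention time and peak area. \code{n_found} is
#' always surfaced so missing analytes depress the count rather than
#' silently distorting the means.
#'
#' @param records data.frame from [runBatch()].
#' @return data.frame with one row per query: \code{query_name},
#'   \code{n_runs}, \code{n_found}, \code{rt_mean}, \code{rt_sd},
#'   \code{rt_rsd}, \code{area_mean}, \code{area_sd}, \code{area_rsd}.
#' @export
summarizeBatch <- function(records) {
  stopifnot(all(c("query_name", "found", "apex_rt", "area") %in%
                names(records)))
  qn <- unique(records$query_name)
  rsd <- function(m, s, n) if (n >= 2 && !is.na(m) && m > 0) s / m * 100
                           else NA_real_
  do.call(rbind, lapply(qn, function(q) {
    sub <- records[records$query_name == q, , drop = FALSE]
    f <- sub[sub$found, , drop = FALSE]
    n <- nrow(f)
    rtm <- if (n) mean(f$apex_rt) else NA_real_
    rts <- if (n >= 2) stats::sd(f$apex_rt) else NA_real_
    am <- if (n) mean(f$area) else NA_real_
    as_ <- if (n >= 2) stats::sd(f$area) else NA_real_
    data.frame(query_name = q, n_runs = nrow(sub), n_found = n,
               rt_mean = rtm, rt_sd = rts, rt_rsd = rsd(rtm, rts, n),
               area_mean = am, area_sd = as_, area_rsd = rsd(am, as_, n))
  }))
}

#' Flag instrument-performance deficiencies
#'
#' Compares per-run records against a reference of expected apex retention
#' times. Three flag types are emitted:
#' \describe{
#'   \item{MISSING_ANALYTE}{a (run, query) record with \code{found =
#'     FALSE}.}
#'   \item{RT_SHIFT}{apex retention time outside the query's nominal
#'     window (\code{rt_min}/\code{rt_max} in the reference) widened by
#'     \code{rtMargin} minutes on each side; when the reference carries no
#'     window, \code{|apex - expected| > rtMargin} is used.}
#'   \item{ELUTION_ORDER}{within one run, the rank order of apex
#'     retention times across queries differs from the reference order:
#'     any discordant pair triggers the flag (Kendall-style), and a fully
#'     inverted order is reported as a reversal.}
#' }
#' Queries absent from the reference are skipped with a warning.
#'
#' @param records data.frame from [runBatch()].
#' @param reference data.frame with columns \code{query_name},
#'   \code{expected_rt} and optional \code{rt_min}, \code{rt_max}; or a
#'   summary from [summarizeBatch()] of a historical batch (its
#'   \code{rt_mean} becomes the expected RT).
#' @param rtMargin widening margin / shift threshold in minutes
#'   (default 0.1).
#' @return data.frame with columns \code{run_id}, \code{query_name}
#'   (\code{NA} for run-level flags), \code{flag}, \code{detail}; zero
#'   rows when the batch is clean.
#' @export
flagDeviations <- function(records, reference, rtMargin = 0.1) {
  if (!is.null(reference$rt_mean) && is.null(reference$expected_rt))
    reference$expected_rt <- reference$rt_mean
  stopifnot(all(c("query_name", "expected_rt") %in% names(reference)))
  missingRef <- setdiff(unique(records$query_name), reference$query_name)
  if (length(missingRef))
    warning("no reference for query(ies): ",
            paste(missingRef, collapse = ", "), "; skipped")
  recs <- records[records$query_name %in% reference$query_name, , drop = FALSE]
  flags <- list()
  addFlag <- function(runId, queryName, flag, detail)
    flags[[length(flags) + 1L]] <<- data.frame(
      run_id = runId, query_name = queryName, flag = flag, detail = detail)

  hasWin <- all(c("rt_min", "rt_max") %in% names(reference))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    ref <- reference[reference$query_name == r$query_name, ][1, ]
    if (!r$found) {
      addFlag(r$run_id, r$query_name, "MISSING_ANALYTE", "no peak found")
      next
    }
    shifted <- if (hasWin && !is.na(ref$rt_min) && !is.na(ref$rt_max))
      r$apex_rt < ref$rt_min - rtMargin || r$apex_rt > ref$rt_max + rtMargin
    else abs(r$apex_rt - ref$expected_rt) > rtMargin
    if (shifted)
      addFlag(r$run_id, r$query_name, "RT_SHIFT",
              sprintf("apex %.3f min vs expected %.3f min",
                      r$apex_rt, ref$expected_rt))
  }

  for (rid in unique(recs$run_id)) {
    sub <- recs[recs$run_id == rid & recs$found, , drop = FALSE]
    if (nrow(sub) < 2) next
    exp_rt <- reference$expected_rt[match(sub$query_name,
                                          reference$query_name)]
    obsRank <- rank(sub$apex_rt)
    refRank <- rank(exp_rt)
    prs <- utils::combn(nrow(sub), 2)
    disc <- sum(sign(obsRank[prs[1, ]] - obsRank[prs[2, ]]) !=
                sign(refRank[prs[1, ]] - refRank[prs[2, ]]))
    if (disc > 0) {
      total <- ncol(prs)
      detail <- if (disc == total)
        sprintf("full reversal of elution order (%d/%d discordant pairs)",
                disc, total)
      else sprintf("%d/%d discordant pairs", disc, total)
      addFlag(rid, NA_character_, "ELUTION_ORDER", detail)
    }
  }
  if (length(flags)) {
    out <- do.call(rbind, flags)
    rownames(out) <- NULL
    out
  } else data.frame(run_id = character(), query_name = character(),
                    flag = character(), detail = character())
}

#' Export batch tables
#'
#' Writes the records, summary and flags tables as CSV and as single-sheet
#' xlsx workbooks with fixed column order. CSV export is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param records,summary,flags data.frames from [runBatch()],
#'   [summarizeBatch()], [flagDeviations()].
#' @param outputDirectory destination directory (created if needed).
#' @return named character vector of the six file paths, invisibly.
#' @export
exportResults <- function(records, summary, flags, outputDirectory) {
  dir.create(outputDirectory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outputDirectory))
    stop("cannot create output directory: ", outputDirectory)
  tables <- list(records = records, summary = summary, flags = flags)
  out <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    attributes(tab)[setdiff(names(attributes(tab)),
                            c("names", "row.names", "class"))] <- NULL
    csv <- file.path(outputDirectory, paste0(nm, ".csv"))
    utils::write.csv(tab, csv, row.names = FALSE, na = "")
    xlsx <- file.path(outputDirectory, paste0(nm, ".xlsx"))
    writeMinimalXlsx(tab, xlsx, sheetName = nm)
    out[paste0(nm, "_csv")] <- csv
    out[paste0(nm, "_xlsx")] <- xlsx
  }
  invisible(out)
}
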