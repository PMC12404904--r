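#' @include sst-batch.R msms.R
NULL

.runPalette <- function(n)
  grDevices::hcl.colors(max(n, 2L), "Dark 3")[seq_len(n)]

.plotEicOverlay <- function(eics, queryName) {
  sel <- Filter(function(e) e@queryName == queryName, eics)
  if (!length(sel)) return(invisible(FALSE))
  cols <- .runPalette(length(sel))
  xr <- range(unlist(lapply(sel, function(e) range(e@rt))))
  yr <- c(0, max(unlist(lapply(sel, function(e) max(c(e@intensity, 0))))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "retention time (min)",
                 ylab = "intensity", main = paste0("EIC: ", queryName))
  for (i in seq_along(sel))
    graphics::lines(sel[[i]]@rt, sel[[i]]@intensity, col = cols[i], lwd = 1.5)
  graphics::legend("topright", legend = vapply(sel, function(e) e@runId,
                                               character(1)),
                   col = cols, lwd = 1.5, cex = 0.7, bty = "n")
  invisible(TRUE)
}

.plotRtBarbell <- function(summary) {
  s <- summary[!is.na(summary$rt_mean), , drop = FALSE]
  if (!nrow(s)) return(invisible(FALSE))
  n <- nrow(s)
  sdv <- ifelse(is.na(s$rt_sd), 0, s$rt_sd)
  xr <- range(c(s$rt_mean - sdv, s$rt_mean + sdv))
  graphics::plot(NA, xlim = xr + c(-0.05, 0.05), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "retention time (min)", ylab = "",
                 main = "Retention time: mean +/- sd per query")
  graphics::axis(2, at = seq_len(n), labels = s$query_name, las = 2,
                 cex.axis = 0.7)
  graphics::segments(s$rt_mean - sdv, seq_len(n), s$rt_mean + sdv, seq_len(n))
  graphics::points(s$rt_mean - sdv, seq_len(n), pch = 19, col = "blue")
  graphics::points(s$rt_mean + sdv, seq_len(n), pch = 19, col = "red")
  graphics::points(s$rt_mean, seq_len(n), pch = 19, col = "black")
  invisible(TRUE)
}

.plotAreaBars <- function(summary) {
  s <- summary[!is.na(summary$area_mean), , drop = FALSE]
  if (!nrow(s)) return(invisible(FALSE))
  sdv <- ifelse(is.na(s$area_sd), 0, s$area_sd)
  mid <- graphics::barplot(s$area_mean, names.arg = s$query_name,
                           las = 2, cex.names = 0.7,
                           ylim = c(0, max(s$area_mean + sdv) * 1.1),
                           ylab = "peak area (intensity*min)",
                           main = "Mean peak area +/- sd per query")
  nz <- sdv > 0
  if (any(nz))
    graphics::arrows(mid[nz], (s$area_mean - sdv)[nz], mid[nz],
                     (s$area_mean + sdv)[nz], angle = 90, code = 3,
                     length = 0.04)
  invisible(TRUE)
}

.plotProfiles <- function(profiles, targetType) {
  p <- profiles[profiles$target_type == targetType &
                  profiles$activation %in% c("HCD", "CID"), , drop = FALSE]
  if (!nrow(p)) return(invisible(FALSE))
  ttl <- if (targetType == "product") "Product-ion normalized intensity"
         else "Neutral-loss normalized intensity"
  analytes <- unique(p$query_name)
  cols <- c(HCD = "#D55E00", CID = "#0072B2")
  graphics::plot(NA, xlim = range(p$nce), ylim = c(0, 1),
                 xlab = "normalized collision energy (NCE)",
                 ylab = "normalized intensity", main = ttl)
  for (a in analytes) for (act in c("HCD", "CID")) {
    sub <- p[p$query_name == a & p$activation == act, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$nce), ]
    graphics::lines(sub$nce, sub$mean_norm_intensity, col = cols[act],
                    type = "b", pch = 19, cex = 0.6)
    sdv <- ifelse(is.na(sub$sd_norm_intensity), 0, sub$sd_norm_intensity)
    nz <- sdv > 0
    if (any(nz))
      graphics::arrows(sub$nce[nz], (sub$mean_norm_intensity - sdv)[nz],
                       sub$nce[nz], (sub$mean_norm_intensity + sdv)[nz],
                       angle = 90, code = 3, length = 0.02, col = cols[act])
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lwd = 1,
                   pch = 19, bty = "n")
  invisible(TRUE)
}

#' Render the graphical SST report artifacts
#'
#' Writes per-query EIC overlay images (one trace per run), a
#' retention-time barbell plot (mean +/- sd per query), a mean peak-area
#' bar plot, and MS/MS normalized-intensity-vs-NCE plots per target type
#' where profiles are supplied. Plot types with empty inputs are skipped
#' with a message. Rendering is read-only with respect to the computed
#' tables.
#'
#' @param records data.frame from [runBatch()] (its \code{"eics"}
#'   attribute supplies the traces when \code{eics} is \code{NULL}).
#' @param summary data.frame from [summarizeBatch()].
#' @param outDir output directory for PNG files.
#' @param eics optional list of [Eic-class] objects.
#' @param profiles optional data.frame from [aggregateProfiles()].
#' @return character vector of image paths, invisibly.
#' @export
renderPlots <- function(records, summary, outDir, eics = NULL,
                        profiles = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(eics)) eics <- attr(records, "eics")
  paths <- character()
  png1 <- function(name, expr) {
    p <- file.path(outDir, paste0(name, ".png"))
    grDevices::png(p, width = 900, height = 600, res = 110)
    ok <- tryCatch(expr, finally = grDevices::dev.off())
    if (isTRUE(ok)) paths[name] <<- p else message("skipped plot: ", name)
  }
  if (length(eics))
    for (qn in unique(records$query_name))
      png1(paste0("eic_", qn), .plotEicOverlay(eics, qn))
  else message("skipped EIC overlays: no traces available")
  png1("rt_barbell", .plotRtBarbell(summary))
  png1("area_bars", .plotAreaBars(summary))
  if (!is.null(profiles) && nrow(profiles)) {
    png1("msms_product", .plotProfiles(profiles, "product"))
    png1("msms_neutral_loss", .plotProfiles(profiles, "neutral_loss"))
  }
  invisible(paths)
}

.tablePage <- function(df, title, maxRows = 25L) {
  graphics::plot.new()
  graphics::title(main = title)
  df <- utils::head(df, maxRows)
  txt <- c(paste(names(df), collapse = "  |  "),
           apply(df, 1, function(r) paste(
             vapply(r, function(v) {
               if (is.na(v)) "" else {
                 vn <- suppressWarnings(as.numeric(v))
                 if (!is.na(vn)) format(signif(vn, 6)) else as.character(v)
               }
             }, character(1)), collapse = "  |  ")))
  graphics::text(0, seq(0.95, by = -0.9 / (length(txt) + 1),
                        length.out = length(txt)),
                 txt, adj = 0, cex = 0.55, family = "mono")
}

#' Assemble the combined PDF report
#'
#' One section (page) per named query with its EIC overlay, followed by
#' the retention-time and peak-area summary plots, MS/MS profile plots
#' when available, and the tabulated summary and flags.
#'
#' @inheritParams renderPlots
#' @param flags data.frame from [flagDeviations()], or \code{NULL}.
#' @param pdfPath output PDF path.
#' @return \code{pdfPath}, invisibly.
#' @export
buildReport <- function(records, summary, pdfPath, flags = NULL, eics = NULL,
                        profiles = NULL) {
  if (is.null(eics)) eics <- attr(records, "eics")
  grDevices::pdf(pdfPath, width = 9, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off())
  if (length(eics))
    for (qn in unique(records$query_name)) .plotEicOverlay(eics, qn)
  .plotRtBarbell(summary)
  .plotAreaBars(summary)
  if (!is.null(profiles) && nrow(profiles)) {
    .plotProfiles(profiles, "product")
    .plotProfiles(profiles, "neutral_loss")
  }
  .tablePage(summary, "Cross-run summary")
  if (!is.null(flags))
    .tablePage(if (nrow(flags)) flags else
                 data.frame(note = "no deficiencies flagged"),
               "Deficiency flags")
  invisible(pdfPath)
}

#' Command-line batch entry point
#'
#' Executes the full pipeline (batch evaluation, summary statistics,
#' deficiency flagging, table export, plots, PDF report) from a JSON
#' configuration. Intended to back the \code{sstlab run} command in
#' \code{inst/scripts/sstlab.R}; callable directly from R.
#'
#' @param configPath path to the JSON configuration.
#' @param mzmlDir,queryFile,outDir optional overrides of the
#'   corresponding configuration keys.
#' @return invisibly, a list with \code{status} (0 = clean, 2 =
#'   configuration error, 3 = partial per-file failure), \code{records},
#'   \code{summary}, \code{flags} and the artifact \code{paths}.
#' @export
cliRun <- function(configPath = NULL, mzmlDir = NULL, queryFile = NULL,
                   outDir = NULL) {
  cfg <- tryCatch({
    cfg <- if (!is.null(configPath)) loadConfig(configPath)
           else list(min_scans = 3L, apex_floor = 0, rt_margin = 0.1)
    if (!is.null(mzmlDir)) cfg$mzml_directory <- mzmlDir
    if (!is.null(queryFile)) cfg$query_file <- queryFile
    if (!is.null(outDir)) cfg$output_directory <- outDir
    for (k in c("mzml_directory", "query_file"))
      if (is.null(cfg[[k]])) stop("missing required setting '", k, "'")
    if (!dir.exists(cfg$mzml_directory))
      stop("mzML directory does not exist: ", cfg$mzml_directory)
    if (!length(.listRuns(cfg$mzml_directory)))
      stop("no mzML files in ", cfg$mzml_directory)
    cfg
  }, error = function(e) e)
  if (inherits(cfg, "error")) {
    message("configuration error: ", conditionMessage(cfg))
    return(invisible(list(status = 2L, error = conditionMessage(cfg))))
  }

  t0 <- Sys.time()
  records <- runBatch(cfg)
  summary <- summarizeBatch(records)
  reference <- if (!is.null(cfg$reference_file) &&
                   file.exists(cfg$reference_file))
    utils::read.csv(cfg$reference_file) else NULL
  flags <- if (!is.null(reference))
    flagDeviations(records, reference, rtMargin = cfg$rt_margin %||% 0.1)
  else data.frame(run_id = character(), query_name = character(),
                  flag = character(), detail = character())
  tables <- exportResults(records, summary, flags, cfg$output_directory)
  imgs <- renderPlots(records, summary, file.path(cfg$output_directory,
                                                  "plots"))
  pdfPath <- file.path(cfg$output_directory, "sst_report.pdf")
  buildReport(records, summary, pdfPath, flags = flags)

  for (i in seq_len(nrow(records)))
    message(sprintf("[%s] run=%s query=%s found=%s apex_rt=%s ppm=%s",
                    format(Sys.time(), "%H:%M:%S"), records$run_id[i],
                    records$query_name[i], records$found[i],
                    format(records$apex_rt[i], digits = 5),
                    format(records$ppm_error[i], digits = 3)))
  message(sprintf("batch of %d records in %.1f s",
                  nrow(records), as.numeric(Sys.time() - t0, units = "secs")))
  nErr <- nrow(attr(records, "errors"))
  status <- if (nErr > 0) 3L else 0L
  if (nErr > 0) message(nErr, " per-file failure(s); see records attribute")
  invisible(list(status = status, records = records, summary = summary,
                 flags = flags,
                 paths = c(tables, imgs, report = pdfPath)))
}

#' Command-line fixture generator entry point
#'
#' Writes a synthetic SST fixture bundle (runs, query file, configuration,
#' reference table); backs the \code{sstlab synth} command.
#'
#' @param outDir output directory.
#' @param seed integer seed.
#' @param variant \code{"default"}, \code{"reversed"} or \code{"shifted"}.
#' @param nRuns number of replicate runs.
#' @param dda write DDA runs with MS2 scans.
#' @return invisibly, a list with \code{status} and the bundle paths.
#' @export
cliSynth <- function(outDir, seed = 1L, variant = "default", nRuns = 3L,
                     dda = FALSE) {
  res <- tryCatch(writeSstFixture(outDir, seed = seed, variant = variant,
                                  nRuns = nRuns, dda = dda),
                  error = function(e) e)
  if (inherits(res, "error")) {
    message("fixture generation failed: ", conditionMessage(res))
    return(invisible(list(status = 2L, error = conditionMessage(res))))
  }
  message("fixture bundle written under ", outDir)
  invisible(c(list(status = 0L), res))
}
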