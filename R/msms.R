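#' @include AllClasses.R AllGenerics.R formula-mass.R
NULL

#' Select MS2 scans by precursor
#'
#' Fragmentation scans whose recorded precursor m/z lies within tolerance
#' of a target, optionally restricted to a retention-time window
#' (boundaries inclusive). An empty selection is a valid result.
#'
#' @param run an [MsRun-class].
#' @param precursorMz target precursor m/z.
#' @param tol tolerance, e.g. \code{tolerancePpm(10)}.
#' @param rtWindow optional numeric(2) window in minutes.
#' @return list of [MsSpectrum-class] scans.
#' @export
selectMs2Scans <- function(run, precursorMz, tol = tolerancePpm(10),
                           rtWindow = NULL) {
  stopifnot(is(run, "MsRun"), precursorMz > 0)
  Filter(function(s) {
    s@msLevel >= 2L && !is.na(s@precursorMz) &&
      withinTolerance(s@precursorMz, precursorMz, tol) &&
      (is.null(rtWindow) ||
         (s@rtMinutes >= rtWindow[1] && s@rtMinutes <= rtWindow[2]))
  }, run@scans)
}

#' TIC-normalized intensity of a product ion or neutral-loss product
#'
#' Sums the intensities of peaks matching the target -- a direct m/z match
#' for product ions, or peaks \code{p} with \code{precursorMz - p} within
#' tolerance of the loss for neutral losses -- and divides by the scan's
#' total ion current, yielding a fraction in \[0, 1\]. Normalizing to the
#' scan TIC accounts for the varying total signal of MS2 scans acquired
#' across a chromatographic peak. A zero-TIC scan yields \code{NA} with a
#' warning and is excluded from aggregation.
#'
#' @param scan an [MsSpectrum-class] with \code{msLevel >= 2}.
#' @param target product-ion m/z, or neutral-loss mass in Da when
#'   \code{type = "neutral_loss"}.
#' @param tol tolerance, e.g. \code{tolerancePpm(10)}.
#' @param type \code{"product"} or \code{"neutral_loss"}.
#' @return numeric fraction in \[0, 1\], or \code{NA} for a zero-TIC scan.
#' @export
normalizedProductIntensity <- function(scan, target, tol = tolerancePpm(10),
                                       type = c("product", "neutral_loss")) {
  type <- match.arg(type)
  stopifnot(is(scan, "MsSpectrum"))
  if (scan@msLevel < 2L) stop("normalization requires an MS2 (or higher) scan")
  total <- sum(scan@intensity)
  if (total <= 0) {
    warning("zero-TIC scan ", scan@scanId, "; normalized intensity is NA")
    return(NA_real_)
  }
  hit <- if (type == "product") {
    withinTolerance(scan@mz, target, tol)
  } else {
    if (is.na(scan@precursorMz))
      stop("neutral-loss matching requires a recorded precursor m/z")
    losses <- scan@precursorMz - scan@mz
    losses > 0 & withinTolerance(losses, target, tol)
  }
  sum(scan@intensity[hit]) / total
}

#' Aggregate product-ion profiles by activation type and collision energy
#'
#' For each analyte in the panel, selects its MS2 scans across all runs,
#' computes the TIC-normalized intensity of the configured product ion
#' and/or neutral loss per scan, and aggregates the mean and sample
#' standard deviation per (analyte, target, activation, NCE) group. NCE
#' values are grouped by exact stated value (floating values matched with
#' 1e-3 tolerance); scans lacking activation or collision-energy metadata
#' are grouped under \code{"unknown"} and reported separately.
#'
#' @param runs list of [MsRun-class] objects (e.g. consecutive days).
#' @param panel data.frame with columns \code{name}, \code{precursor_mz},
#'   optional \code{rt_min}/\code{rt_max}, and targets: \code{product_mz}
#'   and/or \code{nl_formula} (a neutral-loss formula, e.g. \code{"C3H9N"}
#'   or \code{"C3H6D3N"}) or \code{nl_mass}.
#' @param tol tolerance for both scan selection and peak matching.
#' @return data.frame with columns \code{query_name}, \code{target_type},
#'   \code{target}, \code{activation}, \code{nce}, \code{n_scans},
#'   \code{mean_norm_intensity}, \code{sd_norm_intensity}.
#' @export
aggregateProfiles <- function(runs, panel, tol = tolerancePpm(10)) {
  if (is(runs, "MsRun")) runs <- list(runs)
  stopifnot(length(runs) >= 1, "name" %in% names(panel),
            "precursor_mz" %in% names(panel))
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    a <- panel[i, ]
    win <- if (all(c("rt_min", "rt_max") %in% names(panel)) &&
               !is.na(a$rt_min) && !is.na(a$rt_max))
      c(a$rt_min, a$rt_max) else NULL
    targets <- list()
    if (!is.null(panel$product_mz) && !is.na(a$product_mz))
      targets[["product"]] <- a$product_mz
    if (!is.null(panel$nl_mass) && !is.na(a$nl_mass))
      targets[["neutral_loss"]] <- a$nl_mass
    else if (!is.null(panel$nl_formula) && !is.na(a$nl_formula))
      targets[["neutral_loss"]] <- monoisotopicMass(a$nl_formula)
    if (!length(targets)) next

    scans <- unlist(lapply(runs, selectMs2Scans, precursorMz = a$precursor_mz,
                           tol = tol, rtWindow = win), recursive = FALSE)
    if (!length(scans)) next
    act <- vapply(scans, function(s) s@activation, character(1))
    nce <- vapply(scans, function(s) s@collisionEnergy, numeric(1))
    grp <- ifelse(act %in% c("HCD", "CID") & !is.na(nce),
                  paste(act, round(nce / 1e-3) * 1e-3), "unknown")
    for (tt in names(targets)) {
      vals <- vapply(scans, normalizedProductIntensity,
                     numeric(1), target = targets[[tt]], tol = tol, type = tt)
      for (g in unique(grp)) {
        v <- vals[grp == g & !is.na(vals)]
        if (!length(v)) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_name = a$name, target_type = tt, target = targets[[tt]],
          activation = if (g == "unknown") "unknown"
                       else strsplit(g, " ")[[1]][1],
          nce = if (g == "unknown") NA_real_
                else as.numeric(strsplit(g, " ")[[1]][2]),
          n_scans = length(v), mean_norm_intensity = mean(v),
          sd_norm_intensity = if (length(v) >= 2) stats::sd(v) else NA_real_)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(query_name = character(), target_type = character(),
                  target = numeric(), activation = character(),
                  nce = numeric(), n_scans = integer(),
                  mean_norm_intensity = numeric(),
                  sd_norm_intensity = numeric())
  out <- out[order(out$query_name, out$target_type, out$activation, out$nce), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
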