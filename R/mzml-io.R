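#' @include AllClasses.R AllGenerics.R
NULL

# CV accessions used on both the read and write paths.
.CV <- c(
  msLevel = "MS:1000511", centroid = "MS:1000127", profile = "MS:1000128",
  scanStart = "MS:1000016", selectedIon = "MS:1000744",
  isoTarget = "MS:1000827", isoLower = "MS:1000828", isoUpper = "MS:1000829",
  hcd = "MS:1000422", cid = "MS:1000133", collisionEnergy = "MS:1000045",
  mzArray = "MS:1000514", intArray = "MS:1000515",
  f64 = "MS:1000523", f32 = "MS:1000521",
  noCompression = "MS:1000576", zlib = "MS:1000574"
)

.b64encDoubles <- function(x) {
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                               size = 8, endian = "little")),
       fixed = TRUE)
}

#' Read an mzML run
#'
#' Parses an mzML 1.1.x file (plain or indexed; gzip-compressed input is
#' accepted) into an [MsRun-class]. Retention times stored in seconds are
#' converted to minutes per the file's unit annotation; activation type and
#' collision energy are taken from the precursor activation element,
#' defaulting to \code{"unknown"}/\code{NA} when absent. The total ion
#' current of every scan is recomputed from its intensity array. Spectra
#' advertised as profile mode trigger a warning and are loaded as centroid
#' peaks. Retention-time order violations in the source are reported as a
#' warning, never reordered silently.
#'
#' @param path path to an mzML file.
#' @return an [MsRun-class].
#' @seealso [writeMzML()]
#' @export
readMzML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mzml <- if (xml2::xml_name(doc) == "mzML") doc
          else xml2::xml_find_first(doc, ".//mzML")
  if (inherits(mzml, "xml_missing"))
    stop("not an mzML document: ", path)
  ver <- xml2::xml_attr(mzml, "version")
  if (!is.na(ver) && !startsWith(ver, "1.1"))
    warning("unsupported mzML schema version '", ver,
            "' in ", path, "; attempting to read anyway")

  runNode <- xml2::xml_find_first(mzml, ".//run")
  runIdAttr <- xml2::xml_attr(runNode, "id")
  acqDate <- xml2::xml_attr(runNode, "startTimeStamp")
  stem <- sub("\\.gz$", "", basename(path))
  stem <- sub("\\.mzML$", "", stem, ignore.case = TRUE)
  rid <- if (!is.na(runIdAttr) && nzchar(runIdAttr)) runIdAttr else stem

  specNodes <- xml2::xml_find_all(mzml, ".//spectrumList/spectrum")
  emptyNs <- character()
  otherActivation <- c("MS:1000044", "MS:1000262", "MS:1000282",
                       "MS:1000435", "MS:1000598", "MS:1000599")
  profileSeen <- FALSE
  scans <- vector("list", length(specNodes))
  for (i in seq_along(specNodes)) {
    sp <- specNodes[[i]]
    # one flattened cvParam pass per spectrum; accessions disambiguate
    cvs <- xml2::xml_find_all(sp, ".//cvParam", ns = emptyNs)
    accs <- xml2::xml_attr(cvs, "accession", ns = emptyNs)
    vals <- xml2::xml_attr(cvs, "value", ns = emptyNs)
    units <- xml2::xml_attr(cvs, "unitName", ns = emptyNs)
    cv1 <- function(acc) {
      j <- match(acc, accs)
      if (is.na(j)) NA_character_ else vals[j]
    }
    num1 <- function(acc) suppressWarnings(as.numeric(cv1(acc)))

    lvl <- suppressWarnings(as.integer(cv1(.CV["msLevel"])))
    if (is.na(lvl)) lvl <- 1L
    if (!profileSeen && .CV["profile"] %in% accs) {
      profileSeen <- TRUE
      warning("profile-mode spectra advertised in ", path,
              "; treating points as centroid peaks")
    }

    j <- match(.CV["scanStart"], accs)
    rt <- if (is.na(j)) 0 else suppressWarnings(as.numeric(vals[j]))
    if (is.na(rt)) rt <- 0
    if (!is.na(j) && !is.na(units[j]) && tolower(units[j]) == "second")
      rt <- rt / 60

    precMz <- NA_real_; isoWidth <- NA_real_
    act <- "unknown"; nce <- NA_real_
    if (lvl >= 2L) {
      precMz <- num1(.CV["selectedIon"])
      if (is.na(precMz)) precMz <- num1(.CV["isoTarget"])
      lo <- num1(.CV["isoLower"]); hi <- num1(.CV["isoUpper"])
      if (!is.na(lo) && !is.na(hi)) isoWidth <- lo + hi
      act <- if (.CV["hcd"] %in% accs) "HCD"
             else if (.CV["cid"] %in% accs) "CID"
             else if (any(otherActivation %in% accs)) "other"
             else "unknown"
      nce <- num1(.CV["collisionEnergy"])
    }

    mzv <- numeric(); inten <- numeric()
    for (ba in xml2::xml_find_all(sp, "./binaryDataArrayList/binaryDataArray", ns = emptyNs)) {
      bacc <- xml2::xml_attr(xml2::xml_find_all(ba, "./cvParam", ns = emptyNs),
                             "accession", ns = emptyNs)
      size <- if (.CV["f32"] %in% bacc) 4L else 8L
      compressed <- .CV["zlib"] %in% bacc
      txt <- xml2::xml_text(xml2::xml_find_first(ba, "./binary", ns = emptyNs))
      arr <- if (nzchar(trimws(txt))) {
        r <- jsonlite::base64_dec(txt)
        if (compressed) r <- memDecompress(r, type = "gzip")
        readBin(r, "double", n = length(r) %/% size, size = size,
                endian = "little")
      } else numeric()
      if (.CV["mzArray"] %in% bacc) mzv <- arr
      else if (.CV["intArray"] %in% bacc) inten <- arr
    }

    scans[[i]] <- new("MsSpectrum",
      scanId = xml2::xml_attr(sp, "id", ns = emptyNs), msLevel = lvl, rtMinutes = rt,
      mz = mzv, intensity = inten,
      precursorMz = if (lvl >= 2L) precMz else NA_real_,
      isolationWidthMz = isoWidth, activation = act, collisionEnergy = nce)
  }

  rt <- vapply(scans, function(s) s@rtMinutes, numeric(1))
  out <- new("MsRun", runId = rid,
             acquisitionDate = if (is.na(acqDate)) NA_character_ else acqDate)
  if (length(rt) > 1 && any(diff(rt) < 0))
    warning("retention times are not monotone in ", path,
            "; scan order preserved as stored")
  # direct slot fill: source order is preserved even when it violates the
  # monotonicity invariant (reported above, never fixed silently)
  out@scans <- scans
  out
}

.activationXml <- function(act, nce) {
  cv <- switch(act,
    HCD = sprintf('<cvParam cvRef="MS" accession="%s" name="beam-type collision-induced dissociation" value=""/>', .CV["hcd"]),
    CID = sprintf('<cvParam cvRef="MS" accession="%s" name="collision-induced dissociation" value=""/>', .CV["cid"]),
    '<cvParam cvRef="MS" accession="MS:1000044" name="dissociation method" value=""/>')
  if (!is.na(nce))
    cv <- paste0(cv, sprintf(
      '<cvParam cvRef="MS" accession="%s" name="collision energy" value="%s" unitCvRef="UO" unitAccession="UO:0000266" unitName="electronvolt"/>',
      .CV["collisionEnergy"], .fmtNum(nce)))
  cv
}

.spectrumXml <- function(s, index) {
  n <- length(s@mz)
  emz <- .b64encDoubles(s@mz)
  eint <- .b64encDoubles(s@intensity)
  typeCv <- if (s@msLevel == 1L)
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
  precXml <- ""
  if (s@msLevel >= 2L) {
    halfIso <- if (is.na(s@isolationWidthMz)) NA_real_ else s@isolationWidthMz / 2
    isoXml <- if (!is.na(halfIso)) sprintf(paste0(
      '<isolationWindow>',
      '<cvParam cvRef="MS" accession="%s" name="isolation window target m/z" value="%s" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="%s" name="isolation window lower offset" value="%s" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="%s" name="isolation window upper offset" value="%s" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow>'),
      .CV["isoTarget"], .fmtNum(s@precursorMz),
      .CV["isoLower"], .fmtNum(halfIso), .CV["isoUpper"], .fmtNum(halfIso))
    else ""
    precXml <- sprintf(paste0(
      '<precursorList count="1"><precursor>%s',
      '<selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="%s" name="selected ion m/z" value="%s" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</selectedIon></selectedIonList>',
      '<activation>%s</activation></precursor></precursorList>'),
      isoXml, .CV["selectedIon"], .fmtNum(s@precursorMz),
      .activationXml(s@activation, s@collisionEnergy))
  }
  sprintf(paste0(
    '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="%s" name="ms level" value="%d"/>',
    '%s',
    '<cvParam cvRef="MS" accession="%s" name="centroid spectrum" value=""/>',
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="MS" accession="%s" name="scan start time" value="%s" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>',
    '%s',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="%s" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="%s" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="%s" name="no compression" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="%s" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="%s" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="%s" name="no compression" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    index, s@scanId, n, .CV["msLevel"], s@msLevel, typeCv, .CV["centroid"],
    .CV["scanStart"], .fmtNum(s@rtMinutes), precXml,
    nchar(emz), .CV["mzArray"], .CV["f64"], .CV["noCompression"], emz,
    nchar(eint), .CV["intArray"], .CV["f64"], .CV["noCompression"], eint)
}

#' Write an mzML run
#'
#' Emits schema-valid mzML 1.1.0 (centroid spectra, retention times
#' annotated in minutes, 64-bit uncompressed peak arrays) such that
#' \code{readMzML(writeMzML(run, path))} reproduces \code{run} up to
#' floating-point round trip. The run is validated before anything is
#' written.
#'
#' @param run an [MsRun-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readMzML()]
#' @export
writeMzML <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  validObject(run)
  for (s in run@scans) validObject(s)
  specs <- character(length(run@scans))
  for (i in seq_along(run@scans))
    specs[i] <- .spectrumXml(run@scans[[i]], i - 1L)
  tsAttr <- if (!is.na(run@acquisitionDate))
    sprintf(' startTimeStamp="%s"', run@acquisitionDate) else ""
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="mzSST" version="0.1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="mzSST"/>',
    '</software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="mzSST">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="%s" defaultInstrumentConfigurationRef="IC1"%s>',
    '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n%s\n</spectrumList>',
    '</run></mzML>\n'),
    run@runId, tsAttr, length(specs), paste(specs, collapse = "\n"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(doc), con)
  invisible(path)
}

# Shortest decimal rendering that round-trips the double exactly.
.fmtNum <- function(x) {
  if (is.na(x)) return("NA")
  for (d in 1:17) {
    s <- trimws(formatC(x, digits = d, format = "g"))
    if (as.numeric(s) == x) return(s)
  }
  trimws(formatC(x, digits = 17, format = "g"))
}
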