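#' Write a data.frame as a minimal single-sheet xlsx workbook
#'
#' A self-contained Office Open XML writer covering exactly what the batch
#' exporter needs: one sheet, a header row, inline strings for text and
#' plain numeric cells (logicals as TRUE/FALSE strings, NA as empty).
#' Output is readable by spreadsheet applications and by
#' \code{readxl::read_excel}, which serves as the read-back check in the
#' test suite.
#'
#' @param df a data.frame.
#' @param path output path ending in \code{.xlsx}.
#' @param sheetName worksheet name.
#' @return \code{path}, invisibly.
#' @export
writeMinimalXlsx <- function(df, path, sheetName = "Sheet1") {
  stopifnot(is.data.frame(df))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  colRef <- function(j) {
    ref <- ""
    while (j > 0) {
      ref <- paste0(LETTERS[(j - 1L) %% 26L + 1L], ref)
      j <- (j - 1L) %/% 26L
    }
    ref
  }
  cellXml <- function(val, ref) {
    if (is.na(val)) return(sprintf('<c r="%s"/>', ref))
    if (is.numeric(val))
      sprintf('<c r="%s"><v>%s</v></c>', ref, .fmtNum(val))
    else
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
              esc(as.character(val)))
  }
  rowsXml <- character(nrow(df) + 1L)
  hdr <- vapply(seq_along(df), function(j)
    cellXml(names(df)[j], paste0(colRef(j), 1L)), character(1))
  rowsXml[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (is.logical(v) && !is.na(v)) v <- if (v) "TRUE" else "FALSE"
      if (is.factor(v)) v <- as.character(v)
      cellXml(v, paste0(colRef(j), i + 1L))
    }, character(1))
    rowsXml[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                               paste(cells, collapse = ""))
  }

  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  w <- function(rel, txt) writeLines(txt, file.path(tmp, rel), sep = "")

  w("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'))
  w("_rels/.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'))
  w("xl/workbook.xml", sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    esc(sheetName)))
  w("xl/_rels/workbook.xml.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'))
  w("xl/worksheets/sheet1.xml", sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>%s</sheetData></worksheet>'),
    paste(rowsXml, collapse = "")))

  if (file.exists(path)) unlink(path)
  dest <- normalizePath(path, mustWork = FALSE)
  old <- setwd(tmp)
  on.exit({ setwd(old); unlink(tmp, recursive = TRUE) })
  zip::zip(zipfile = dest,
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
           recurse = FALSE, include_directories = FALSE)
  invisible(path)
}
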