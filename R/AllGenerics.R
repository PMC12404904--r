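#' @include AllClasses.R
NULL

#' @export
setGeneric("runId", function(object) standardGeneric("runId"))

#' @export
setGeneric("acquisitionDate", function(object) standardGeneric("acquisitionDate"))

#' @export
setGeneric("scans", function(object) standardGeneric("scans"))

#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))

#' @export
setGeneric("rtMinutes", function(object) standardGeneric("rtMinutes"))

#' @export
setGeneric("msLevel", function(object) standardGeneric("msLevel"))

#' @export
setGeneric("peakMz", function(object) standardGeneric("peakMz"))

#' @export
setGeneric("peakIntensity", function(object) standardGeneric("peakIntensity"))

#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @export
setGeneric("activationType", function(object) standardGeneric("activationType"))

#' @export
setGeneric("collisionEnergy", function(object) standardGeneric("collisionEnergy"))

#' @export
setGeneric("tic", function(object) standardGeneric("tic"))

#' @export
setGeneric("queryAction", function(object) standardGeneric("queryAction"))

#' @export
setGeneric("querySource", function(object) standardGeneric("querySource"))

#' @export
setGeneric("queryConditions", function(object) standardGeneric("queryConditions"))

#' @export
setGeneric("queryTolerance", function(object) standardGeneric("queryTolerance"))

#' @export
setGeneric("rtWindow", function(object) standardGeneric("rtWindow"))

#' @export
setGeneric("peakFound", function(object) standardGeneric("peakFound"))

#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))

#' @export
setGeneric("apexRt", function(object) standardGeneric("apexRt"))

#' @export
setGeneric("apexIntensity", function(object) standardGeneric("apexIntensity"))
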