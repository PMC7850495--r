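#' @include AllClasses.R
NULL

#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @export
setGeneric("repeatUnit", function(x) standardGeneric("repeatUnit"))

#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setGeneric("deltas", function(x) standardGeneric("deltas"))

#' @export
setGeneric("markerCoverage", function(x) standardGeneric("markerCoverage"))

#' @export
setGeneric("truthStatus", function(x) standardGeneric("truthStatus"))

#' @export
setGeneric("truthUnstable", function(x) standardGeneric("truthUnstable"))

#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))

#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @export
setGeneric("msiStatus", function(x) standardGeneric("msiStatus"))

#' @export
setGeneric("unstableFraction", function(x) standardGeneric("unstableFraction"))
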