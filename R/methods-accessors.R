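#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn MarkerPanel panel name.
#' @param x a MarkerPanel.
#' @export
setMethod("panelName", "MarkerPanel", function(x) x@panelName)

#' @describeIn MarkerPanel marker identifiers, in panel order.
#' @export
setMethod("markerIds", "MarkerPanel",
    function(x) S4Vectors::mcols(x@markers)$marker_id)

#' @describeIn MarkerPanel reference tract lengths (bp), named by marker id.
#' @export
setMethod("refLength", "MarkerPanel", function(x)
    stats::setNames(GenomicRanges::width(x@markers), markerIds(x)))

#' @describeIn MarkerPanel repeat-unit motifs, named by marker id.
#' @export
setMethod("repeatUnit", "MarkerPanel", function(x)
    stats::setNames(S4Vectors::mcols(x@markers)$repeat_unit, markerIds(x)))

#' @describeIn MarkerPanel underlying GRanges (1-based inclusive).
#' @export
setMethod("markerRanges", "MarkerPanel", function(x) x@markers)

#' @describeIn MarkerPanel number of markers.
#' @export
setMethod("length", "MarkerPanel", function(x) length(x@markers))

#' @describeIn MarkerPanel subset by position, logical mask or marker id;
#'   the result keeps panel order.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MarkerPanel", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, markerIds(x))
    methods::initialize(x, markers = x@markers[i])
})

setMethod("show", "MarkerPanel", function(object) {
    ru <- repeatUnit(object)
    cat(sprintf("MarkerPanel '%s' with %d marker%s\n", panelName(object),
        length(object), if (length(object) == 1L) "" else "s"))
    if (length(object)) {
        cat(sprintf("  repeat units: %s\n",
            paste(sprintf("%dbp x%d", unique(nchar(ru)),
                tabulate(factor(nchar(ru)))[unique(nchar(ru))]),
                collapse = ", ")))
        cat(sprintf("  tract lengths: %d-%d bp\n",
            min(refLength(object)), max(refLength(object))))
    }
})

#' @describeIn LengthDistributions sample identifier.
#' @param x a LengthDistributions.
#' @export
setMethod("sampleId", "LengthDistributions", function(x) x@sampleId)

#' @describeIn LengthDistributions named IntegerList of per-marker deltas.
#' @export
setMethod("deltas", "LengthDistributions", function(x) x@deltas)

#' @describeIn LengthDistributions per-marker coverage (number of deltas),
#'   named by marker id.
#' @export
setMethod("markerCoverage", "LengthDistributions",
    function(x) lengths(x@deltas))

#' @describeIn LengthDistributions number of markers.
#' @export
setMethod("length", "LengthDistributions", function(x) length(x@deltas))

setMethod("show", "LengthDistributions", function(object) {
    cov <- markerCoverage(object)
    cat(sprintf(
        "LengthDistributions for sample '%s': %d markers, coverage %s\n",
        sampleId(object), length(object),
        if (length(cov)) sprintf("%d-%d (median %d)", min(cov), max(cov),
            as.integer(stats::median(cov))) else "-"))
})

#' @describeIn SampleResult sample identifier.
#' @param x a SampleResult.
#' @export
setMethod("sampleId", "SampleResult", function(x) x@sampleId)

#' @describeIn SampleResult final status string.
#' @export
setMethod("msiStatus", "SampleResult", function(x) x@status)

#' @describeIn SampleResult unstable fraction (NA when indeterminate).
#' @export
setMethod("unstableFraction", "SampleResult", function(x) x@unstableFraction)

setMethod("show", "SampleResult", function(object) {
    cat(sprintf("SampleResult '%s' (%s): %s\n", object@sampleId,
        object@sampleType, object@status))
    cat(sprintf("  unstable %d / valid %d of %d markers (fraction %s, cutoff %.2f)\n",
        object@nUnstable, object@nValid, object@nMarkers,
        ifelse(is.na(object@unstableFraction), "NA",
               sprintf("%.3f", object@unstableFraction)),
        object@cutoff))
})

#' Flatten a SampleResult to a one-row data.frame
#'
#' @param x a \linkS4class{SampleResult}.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return one-row \code{data.frame} with the slots as columns.
#' @export
as.data.frame.SampleResult <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
    data.frame(sample_id = x@sampleId, sample_type = x@sampleType,
        n_markers = x@nMarkers, n_valid = x@nValid,
        n_unstable = x@nUnstable, unstable_fraction = x@unstableFraction,
        cutoff = x@cutoff, status = x@status,
        row.names = row.names, stringsAsFactors = FALSE)
}

#' @describeIn SimulatedCohort generation parameters.
#' @param x a SimulatedCohort.
#' @export
setMethod("simParams", "SimulatedCohort", function(x) x@params)

#' @describeIn SimulatedCohort named list of per-sample
#'   \linkS4class{LengthDistributions}.
#' @export
setMethod("cohortSamples", "SimulatedCohort", function(x) x@samples)

#' @describeIn SimulatedCohort named character vector of truth labels.
#' @export
setMethod("truthStatus", "SimulatedCohort", function(x) x@truth)

#' @describeIn SimulatedCohort logical matrix (markers x samples) of
#'   truth-unstable flags.
#' @export
setMethod("truthUnstable", "SimulatedCohort", function(x) x@truthUnstable)

#' @describeIn SimulatedCohort number of samples.
#' @export
setMethod("length", "SimulatedCohort", function(x) length(x@samples))

setMethod("show", "SimulatedCohort", function(object) {
    tt <- table(factor(object@truth, c("MSI-H", "MSS")))
    cat(sprintf(
        "SimulatedCohort (%s): %d samples (%d MSI-H, %d MSS) on panel '%s' (%d markers), seed %d\n",
        object@params$sample_type, length(object), tt[["MSI-H"]],
        tt[["MSS"]], panelName(object@panel), length(object@panel),
        object@params$seed))
})
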