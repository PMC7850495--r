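setClassUnion("numeric_OR_NULL", c("numeric", "NULL"))

#' MarkerPanel: a panel of microsatellite markers
#'
#' A \code{MarkerPanel} holds an ordered set of microsatellite loci: genomic
#' interval, repeat unit motif and reference tract length. Intervals are
#' stored 1-based inclusive in the underlying \linkS4class{GRanges} (the
#' on-disk panel format is BED-style 0-based half-open); the reference tract
#' length equals the interval width.
#'
#' Validity requirements: unique marker ids, repeat units of 1-6 bp over
#' \{A,C,G,T\}, markers sorted by (chromosome, start), and no overlapping
#' markers on the same chromosome (two markers at identical coordinates are
#' therefore also rejected: one locus, one statistic).
#'
#' @slot panelName single string naming the panel.
#' @slot markers \linkS4class{GRanges} with metadata columns
#'   \code{marker_id} (character) and \code{repeat_unit} (character).
#'
#' @seealso \code{\link{readMarkerPanel}}, \code{\link{subsetPanel}},
#'   \code{\link{syntheticPanel}}
#' @export
setClass("MarkerPanel",
    slots = c(panelName = "character", markers = "GRanges"))

.validMarkerPanel <- function(object) {
    gr <- object@markers
    msg <- character()
    if (length(object@panelName) != 1L || is.na(object@panelName))
        msg <- c(msg, "'panelName' must be a single non-NA string")
    mc <- S4Vectors::mcols(gr)
    if (!all(c("marker_id", "repeat_unit") %in% colnames(mc)))
        return("markers must carry 'marker_id' and 'repeat_unit' columns")
    ids <- mc$marker_id
    ru <- mc$repeat_unit
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate marker_id: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    bad_ru <- !grepl("^[ACGT]{1,6}$", ru)
    if (any(bad_ru))
        msg <- c(msg, sprintf(
            "repeat_unit must be 1-6 bp over {A,C,G,T} (marker %s)",
            paste(ids[bad_ru], collapse = ", ")))
    if (length(gr) > 1L) {
        o <- order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "markers must be sorted by (chrom, start)")
        hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                            drop.redundant = TRUE)
        if (length(hits) > 0L)
            msg <- c(msg, sprintf("overlapping markers: %s / %s",
                ids[S4Vectors::queryHits(hits)[1L]],
                ids[S4Vectors::subjectHits(hits)[1L]]))
    }
    if (length(msg)) msg else TRUE
}
setValidity("MarkerPanel", .validMarkerPanel)

#' @describeIn MarkerPanel constructor. \code{markers} is a GRanges with
#'   metadata columns \code{marker_id} and \code{repeat_unit}; it is sorted
#'   by (chromosome, start) on construction.
#' @param name single string, panel name.
#' @param markers GRanges of marker loci.
#' @export
MarkerPanel <- function(markers, name = "panel") {
    stopifnot(methods::is(markers, "GRanges"))
    if (length(markers) > 1L) {
        o <- order(as.character(GenomicRanges::seqnames(markers)),
                   GenomicRanges::start(markers))
        markers <- markers[o]
    }
    methods::new("MarkerPanel", panelName = as.character(name),
                 markers = markers)
}

#' LengthDistributions: per-marker normalized tract-length deltas
#'
#' For one sample, the multiset of normalized microsatellite tract lengths
#' observed at each marker of a panel. Each element is an integer delta =
#' observed tract length minus reference tract length (0 for a
#' reference-length read). Coverage of a marker is the number of deltas it
#' holds; a marker with no spanning reads has an empty delta vector.
#'
#' @slot sampleId single string.
#' @slot deltas named \linkS4class{IntegerList}, one element per marker,
#'   names are marker ids.
#' @slot refLength integer vector parallel to \code{deltas}: reference tract
#'   length per marker (used to enforce that no delta contracts a tract below
#'   zero bases). May be \code{NA} when unknown (e.g. a bare length table).
#'
#' @seealso \code{\link{collectLengthDistributions}},
#'   \code{\link{readLengthTable}}, \code{\link{callMarkers}}
#' @export
setClass("LengthDistributions",
    slots = c(sampleId = "character", deltas = "IntegerList",
              refLength = "integer"))

.validLengthDistributions <- function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be a single string")
    nm <- names(object@deltas)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        msg <- c(msg, "deltas must be uniquely named by marker_id")
    if (length(object@refLength) != length(object@deltas))
        msg <- c(msg, "refLength must be parallel to deltas")
    rl <- object@refLength
    known <- !is.na(rl)
    if (any(known)) {
        mins <- suppressWarnings(min(object@deltas[known]))
        mins[lengths(object@deltas[known]) == 0L] <- 0L
        if (any(mins < -rl[known]))
            msg <- c(msg, "delta below -refLength: tract length cannot be negative")
    }
    if (length(msg)) msg else TRUE
}
setValidity("LengthDistributions", .validLengthDistributions)

#' @describeIn LengthDistributions constructor.
#' @param deltas named list (or IntegerList) of integer delta vectors.
#' @param sample_id single string.
#' @param ref_length integer vector of reference tract lengths, recycled or
#'   \code{NA} when unknown.
#' @export
LengthDistributions <- function(deltas, sample_id = "sample",
                                ref_length = NA_integer_) {
    if (!methods::is(deltas, "IntegerList"))
        deltas <- IRanges::IntegerList(lapply(deltas, as.integer))
    rl <- as.integer(rep_len(ref_length, length(deltas)))
    methods::new("LengthDistributions", sampleId = as.character(sample_id),
                 deltas = deltas, refLength = rl)
}

#' SampleResult: sample-level MSI classification
#'
#' Aggregation of per-marker instability calls for one sample: counts of
#' valid (coverage-passing) and unstable markers, the unstable fraction
#' (denominator = valid markers only), the cutoff applied, and the final
#' status: \code{"MSI-H"} when the fraction reaches the cutoff (inclusive),
#' \code{"MSS"} otherwise, \code{"indeterminate"} when no marker is valid.
#'
#' @slot sampleId,sampleType single strings; type is one of
#'   \code{"fresh"}, \code{"cell_line"}, \code{"ffpe"}.
#' @slot nMarkers,nValid,nUnstable integer counts.
#' @slot unstableFraction numeric in [0,1], \code{NA} when indeterminate.
#' @slot cutoff numeric in (0,1).
#' @slot status one of \code{"MSI-H"}, \code{"MSS"}, \code{"indeterminate"}.
#'
#' @seealso \code{\link{classifySample}}, \code{\link{defaultCutoff}}
#' @export
setClass("SampleResult",
    slots = c(sampleId = "character", sampleType = "character",
              nMarkers = "integer", nValid = "integer",
              nUnstable = "integer", unstableFraction = "numeric",
              cutoff = "numeric", status = "character"))

.validSampleResult <- function(object) {
    msg <- character()
    if (!(object@sampleType %in% c("fresh", "cell_line", "ffpe")))
        msg <- c(msg, "sampleType must be fresh, cell_line or ffpe")
    if (!(object@status %in% c("MSI-H", "MSS", "indeterminate")))
        msg <- c(msg, "status must be MSI-H, MSS or indeterminate")
    if (object@nUnstable > object@nValid || object@nValid > object@nMarkers)
        msg <- c(msg, "need nUnstable <= nValid <= nMarkers")
    if (object@cutoff <= 0 || object@cutoff >= 1)
        msg <- c(msg, "cutoff must lie in (0,1)")
    if (object@nValid == 0L) {
        if (object@status != "indeterminate")
            msg <- c(msg, "no valid marker implies indeterminate status")
    } else {
        f <- object@nUnstable / object@nValid
        if (!isTRUE(all.equal(f, object@unstableFraction)))
            msg <- c(msg, "unstableFraction must equal nUnstable/nValid")
        want <- if (f >= object@cutoff) "MSI-H" else "MSS"
        if (object@status != want)
            msg <- c(msg, "status inconsistent with fraction and cutoff")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SampleResult", .validSampleResult)

#' SimulatedCohort: synthetic samples with recorded ground truth
#'
#' Output of \code{\link{simulateCohort}}: per-sample
#' \linkS4class{LengthDistributions} together with the generating parameters,
#' the panel, sample-level truth labels and the per-sample set of
#' truth-unstable markers. In truth-MSS samples no marker is truth-unstable.
#'
#' @slot params validated parameter list from \code{\link{SimParams}}.
#' @slot panel the \linkS4class{MarkerPanel} simulated over.
#' @slot samples named list of \linkS4class{LengthDistributions}.
#' @slot truth named character vector of truth status per sample
#'   (\code{"MSI-H"} / \code{"MSS"}).
#' @slot truthUnstable logical matrix, markers x samples: which markers carry
#'   the unstable (contracted-allele) signal in which sample.
#'
#' @export
setClass("SimulatedCohort",
    slots = c(params = "list", panel = "MarkerPanel", samples = "list",
              truth = "character", truthUnstable = "matrix"))

.validSimulatedCohort <- function(object) {
    msg <- character()
    n <- length(object@samples)
    if (length(object@truth) != n || !identical(names(object@samples),
                                                names(object@truth)))
        msg <- c(msg, "truth labels must be parallel to samples")
    tu <- object@truthUnstable
    if (!identical(colnames(tu), names(object@samples)) ||
        !identical(rownames(tu), markerIds(object@panel)))
        msg <- c(msg, "truthUnstable must be markers x samples")
    mss <- names(object@truth)[object@truth == "MSS"]
    if (length(mss) && any(tu[, mss, drop = FALSE]))
        msg <- c(msg, "MSS samples cannot carry truth-unstable markers")
    if (length(msg)) msg else TRUE
}
setValidity("SimulatedCohort", .validSimulatedCohort)
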