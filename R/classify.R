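#' @include AllClasses.R AllGenerics.R
NULL

#' Tissue-type-specific MSI-H cutoff on the unstable fraction
#'
#' Default cutoffs on the fraction of unstable valid markers: 0.4 for fresh
#' tissue and cell lines, 0.25 for FFPE tissue, where formalin-induced
#' artifacts and lower, more variable coverage depress the observed
#' fraction in truly unstable tumors. Cutoffs were established empirically
#' on colorectal cancer cohorts and are exposed as parameters, not
#' constants.
#'
#' @param sample_type one of \code{"fresh"}, \code{"cell_line"},
#'   \code{"ffpe"}.
#' @return the cutoff fraction.
#' @examples
#' defaultCutoff("fresh")  # 0.4
#' defaultCutoff("ffpe")   # 0.25
#' @export
defaultCutoff <- function(sample_type = c("fresh", "cell_line", "ffpe")) {
    sample_type <- match.arg(sample_type)
    switch(sample_type, fresh = 0.4, cell_line = 0.4, ffpe = 0.25)
}

#' Classify a sample's MSI status from its marker calls
#'
#' Aggregates per-marker calls into a sample-level status. The unstable
#' fraction uses only valid (coverage-passing) markers as denominator --
#' filtered markers are excluded entirely. The comparison with the cutoff
#' is inclusive: a fraction exactly equal to the cutoff is called MSI-H.
#' A sample with no valid marker at all is \code{"indeterminate"} (with a
#' warning), never silently MSS.
#'
#' @param calls DataFrame from \code{\link{callMarkers}} (columns
#'   \code{valid}, \code{unstable}), all from one sample and one panel.
#' @param sample_id sample name.
#' @param sample_type one of \code{"fresh"}, \code{"cell_line"},
#'   \code{"ffpe"}; selects the default cutoff.
#' @param cutoff override of \code{\link{defaultCutoff}}, in (0,1).
#' @return a \linkS4class{SampleResult}.
#' @examples
#' d <- LengthDistributions(list(m1 = rep(0L, 30), m2 = c(rep(0L, 15),
#'     rep(-3L, 15))), sample_id = "s1", ref_length = 20L)
#' classifySample(callMarkers(d), "s1", "fresh")
#' @export
classifySample <- function(calls, sample_id,
                           sample_type = c("fresh", "cell_line", "ffpe"),
                           cutoff = NULL) {
    sample_type <- match.arg(sample_type)
    if (is.null(cutoff)) cutoff <- defaultCutoff(sample_type)
    .assertScalarNumber(cutoff, "cutoff", lower = 0, upper = 1,
                        lower_open = TRUE, upper_open = TRUE)
    calls <- as.data.frame(calls)
    if (nrow(calls) == 0L)
        stop("no marker calls supplied for sample ", sample_id)
    stopifnot(all(c("valid", "unstable") %in% colnames(calls)))
    n_valid <- sum(calls$valid)
    n_unstable <- sum(calls$unstable)
    if (n_valid == 0L) {
        warning("sample ", sample_id,
                ": no marker passed the coverage filter; status indeterminate")
        frac <- NA_real_
        status <- "indeterminate"
    } else {
        frac <- n_unstable / n_valid
        status <- if (frac >= cutoff) "MSI-H" else "MSS"
    }
    methods::new("SampleResult", sampleId = as.character(sample_id),
        sampleType = sample_type, nMarkers = nrow(calls),
        nValid = as.integer(n_valid), nUnstable = as.integer(n_unstable),
        unstableFraction = frac, cutoff = cutoff, status = status)
}

#' Run the full caller over a simulated cohort
#'
#' Convenience wrapper: scores and classifies every sample of a
#' \linkS4class{SimulatedCohort} and tabulates the results next to the
#' truth labels.
#'
#' @param cohort a \linkS4class{SimulatedCohort}.
#' @param cutoff override of the sample-type default cutoff.
#' @param coverage_min,psc_threshold passed to \code{\link{callMarkers}}.
#' @return \code{data.frame} with one row per sample: \code{sample_id},
#'   \code{truth}, \code{n_valid}, \code{n_unstable},
#'   \code{unstable_fraction}, \code{status}.
#' @export
classifyCohort <- function(cohort, cutoff = NULL, coverage_min = 20L,
                           psc_threshold = 1) {
    stopifnot(methods::is(cohort, "SimulatedCohort"))
    stype <- simParams(cohort)$sample_type
    res <- lapply(cohortSamples(cohort), function(s) {
        suppressWarnings(classifySample(
            callMarkers(s, coverage_min = coverage_min,
                        psc_threshold = psc_threshold),
            sample_id = sampleId(s), sample_type = stype, cutoff = cutoff))
    })
    out <- do.call(rbind, lapply(res, as.data.frame))
    out <- out[, c("sample_id", "n_valid", "n_unstable",
                   "unstable_fraction", "status")]
    out$truth <- unname(truthStatus(cohort)[out$sample_id])
    rownames(out) <- NULL
    out[, c("sample_id", "truth", "n_valid", "n_unstable",
            "unstable_fraction", "status")]
}
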