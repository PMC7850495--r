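#' @include AllClasses.R AllGenerics.R
NULL

#' Pearson's skewness coefficient of a length distribution
#'
#' The per-marker instability statistic: \code{3 * (mean(x) - median(x)) /
#' sd(x)}, with \code{sd} the sample (n-1 denominator) standard deviation.
#' A zero-variance distribution -- every read at the same length -- is the
#' most stable possible observation and is scored 0 rather than dividing by
#' zero. Because \eqn{|mean - median| \le sd}, the statistic always lies in
#' \eqn{[-3, 3]}. It is invariant under location shift, so scoring
#' normalized deltas or raw tract lengths gives the same value.
#'
#' @param x non-empty numeric vector (normalized length deltas).
#' @return the skewness coefficient, a number in \eqn{[-3, 3]}.
#' @examples
#' pearsonSkewness(c(-1, 0, 1))          # symmetric: 0
#' pearsonSkewness(c(0, 0, 0, -2, -2))   # deletion-skewed: about -2.19
#' @export
pearsonSkewness <- function(x) {
    if (length(x) == 0L)
        stop("cannot compute skewness of an empty distribution")
    x <- as.numeric(x)
    if (anyNA(x)) stop("deltas must not contain NA")
    s <- stats::sd(x)
    if (length(x) == 1L || s == 0) return(0)
    3 * (mean(x) - stats::median(x)) / s
}

#' Call per-marker instability from length distributions
#'
#' Applies the coverage filter and the skewness rule to every marker of a
#' sample. A marker is \emph{valid} when its coverage strictly exceeds
#' \code{coverage_min} (the default filters out markers at <= 20x);
#' invalid markers get an \code{NA} score and are never unstable. A valid
#' marker is \emph{unstable} when the magnitude of its skewness coefficient
#' strictly exceeds \code{psc_threshold}.
#'
#' @param x a \linkS4class{LengthDistributions}.
#' @param coverage_min coverage at or below which a marker is filtered out
#'   (default 20).
#' @param psc_threshold instability threshold on |PSC| (default 1; strict
#'   inequality).
#' @return a \link[S4Vectors]{DataFrame} with one row per marker and
#'   columns \code{marker_id}, \code{coverage}, \code{psc} (\code{NA} when
#'   invalid), \code{valid}, \code{unstable}.
#' @seealso \code{\link{pearsonSkewness}}, \code{\link{classifySample}}
#' @export
callMarkers <- function(x, coverage_min = 20L, psc_threshold = 1) {
    stopifnot(methods::is(x, "LengthDistributions"))
    .assertScalarNumber(coverage_min, "coverage_min", lower = 0)
    .assertScalarNumber(psc_threshold, "psc_threshold", lower = 0,
                        lower_open = TRUE)
    d <- deltas(x)
    cov <- unname(lengths(d))
    valid <- cov > coverage_min
    psc <- rep(NA_real_, length(d))
    psc[valid] <- vapply(as.list(d[valid]), pearsonSkewness, numeric(1L))
    unstable <- valid & !is.na(psc) & abs(psc) > psc_threshold
    S4Vectors::DataFrame(marker_id = names(d), coverage = cov, psc = psc,
                         valid = valid, unstable = unstable)
}

#' Write per-marker calls to TSV
#'
#' @param calls DataFrame from \code{\link{callMarkers}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMarkerCalls <- function(calls, path) {
    df <- as.data.frame(calls)
    df$psc <- ifelse(is.na(df$psc), "NA", format(df$psc, digits = 15L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
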