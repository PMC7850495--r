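#' @include AllClasses.R AllGenerics.R
NULL

.normStatus <- function(x, what) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
        stop("'", what, "' must be uniquely named by sample id")
    ok <- x %in% c("MSI-H", "MSS", "indeterminate")
    if (!all(ok))
        stop("'", what, "' contains unknown status: ",
             paste(unique(x[!ok]), collapse = ", "))
    x
}

#' Confusion matrix and screening metrics for MSI calls
#'
#' Compares called against true MSI status, with MSI-H as the positive
#' class. Indeterminate calls are excluded from the counts (their number is
#' reported and messaged). A metric whose denominator is zero is \code{NA},
#' never 0.
#'
#' @param truth named character vector of true status per sample
#'   (\code{"MSI-H"} / \code{"MSS"}).
#' @param called named character vector of called status on the same
#'   samples (may include \code{"indeterminate"}).
#' @return named list: \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{n_indeterminate}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy}.
#' @examples
#' tr <- c(s1 = "MSI-H", s2 = "MSS", s3 = "MSS")
#' msiConfusion(tr, c(s1 = "MSI-H", s2 = "MSS", s3 = "MSI-H"))
#' @export
msiConfusion <- function(truth, called) {
    truth <- .normStatus(truth, "truth")
    called <- .normStatus(called, "called")
    if (!setequal(names(truth), names(called)) ||
        length(truth) != length(called))
        stop("'truth' and 'called' must cover the identical sample set")
    called <- called[names(truth)]
    ind <- called == "indeterminate"
    if (any(ind))
        message(sum(ind), " indeterminate call(s) excluded from metrics")
    truth <- truth[!ind]
    called <- called[!ind]
    tp <- sum(truth == "MSI-H" & called == "MSI-H")
    fn <- sum(truth == "MSI-H" & called == "MSS")
    tn <- sum(truth == "MSS" & called == "MSS")
    fp <- sum(truth == "MSS" & called == "MSI-H")
    rate <- function(num, den) if (den == 0L) NA_real_ else num / den
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         n_indeterminate = sum(ind),
         sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         accuracy = rate(tp + tn, tp + fp + tn + fn))
}

#' Paired McNemar comparison of two MSI classifiers
#'
#' Compares two classifiers on the same samples by the correctness of each
#' call against truth. \code{b} counts samples classifier A gets right and
#' B wrong, \code{c} the converse. With few discordant pairs
#' (\code{b + c < 25}) the p-value is the exact two-sided binomial test of
#' \code{b} successes in \code{b + c} trials at probability 1/2; otherwise
#' the continuity-corrected chi-square \eqn{(|b - c| - 1)^2 / (b + c)} on 1
#' df. No discordant pairs at all gives p = 1. Restrict to truth-positive
#' samples to compare sensitivities, to truth-negative samples for
#' specificities.
#'
#' @param calls_a,calls_b named status vectors from the two classifiers,
#'   on identical samples.
#' @param truth named true status vector on the same samples.
#' @param restrict \code{"all"}, \code{"positive"} (truth MSI-H only) or
#'   \code{"negative"} (truth MSS only).
#' @return named list: \code{b}, \code{c}, \code{n}, \code{p.value},
#'   \code{method} (\code{"exact-binomial"} or \code{"chi-square"}).
#' @examples
#' tr <- c(a = "MSI-H", b = "MSI-H", c = "MSS", d = "MSS")
#' ca <- c(a = "MSI-H", b = "MSI-H", c = "MSS", d = "MSS")
#' cb <- c(a = "MSI-H", b = "MSS",   c = "MSS", d = "MSS")
#' mcnemarPaired(ca, cb, tr)
#' @export
mcnemarPaired <- function(calls_a, calls_b, truth,
                          restrict = c("all", "positive", "negative")) {
    restrict <- match.arg(restrict)
    truth <- .normStatus(truth, "truth")
    calls_a <- .normStatus(calls_a, "calls_a")
    calls_b <- .normStatus(calls_b, "calls_b")
    if (!setequal(names(truth), names(calls_a)) ||
        !setequal(names(truth), names(calls_b)))
        stop("calls_a, calls_b and truth must cover the identical samples")
    keep <- switch(restrict, all = rep(TRUE, length(truth)),
                   positive = truth == "MSI-H", negative = truth == "MSS")
    ids <- names(truth)[keep]
    ok_a <- calls_a[ids] == truth[ids]
    ok_b <- calls_b[ids] == truth[ids]
    b <- sum(ok_a & !ok_b)
    cc <- sum(!ok_a & ok_b)
    n <- b + cc
    if (n == 0L) {
        p <- 1
        method <- "exact-binomial"
    } else if (n < 25L) {
        p <- stats::binom.test(b, n, p = 0.5)$p.value
        method <- "exact-binomial"
    } else {
        stat <- (abs(b - cc) - 1)^2 / n
        p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
        method <- "chi-square"
    }
    list(b = b, c = cc, n = n, p.value = p, method = method)
}
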