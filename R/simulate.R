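#' @include AllClasses.R AllGenerics.R
NULL

#' Simulation parameters for synthetic MSI cohorts
#'
#' Validates and completes the parameter set driving
#' \code{\link{simulateCohort}}. Regime-dependent parameters default by
#' \code{sample_type}: fresh tissue and cell lines draw per-marker coverage
#' from a tight negative binomial (dispersion 0.02) with no dropout and no
#' extra artifact noise; FFPE uses a much wider coverage law (dispersion
#' 0.2), resamples a marker's coverage uniformly on [0, 25] with
#' probability \code{dropout_rate} (deliberately straddling the 20x
#' filter), and adds a per-read +/-1 bp artifact with probability
#' \code{ffpe_noise_rate} -- emulating the wider coverage variation and
#' extra length noise that formalin fixation introduces.
#'
#' @param seed integer; the single source of randomness for the cohort.
#' @param n_msih,n_mss numbers of MSI-H and MSS samples.
#' @param sample_type \code{"fresh"}, \code{"cell_line"} or \code{"ffpe"}.
#' @param unstable_marker_rate fraction of panel markers carrying the
#'   unstable signal in an MSI-H sample (default 0.6).
#' @param stutter_rate per-read probability of a +/-1 repeat-unit PCR slip
#'   (default 0.05), applied to every allele.
#' @param shift_units size of the unstable-allele contraction in repeat
#'   units (default 3); a negative value flips the convention to
#'   expansions.
#' @param tumor_fraction probability a read at an unstable marker comes
#'   from the contracted allele (default 0.35: a heterozygous tract
#'   contraction at realistic tumor purity; note that 0.5 makes the
#'   unstable mixture perfectly symmetric, the one regime a skewness
#'   statistic cannot see).
#' @param coverage_mean mean per-marker coverage (default 100).
#' @param coverage_dispersion negative-binomial dispersion of coverage
#'   (variance = mu + dispersion * mu^2); regime default 0.02 fresh /
#'   cell_line, 0.2 ffpe.
#' @param dropout_rate probability a marker's coverage is resampled
#'   uniformly on [0, 25]; regime default 0.15 ffpe, 0 otherwise.
#' @param ffpe_noise_rate per-read probability of an extra +/-1 bp
#'   artifact; regime default 0.05 ffpe, 0 otherwise.
#' @return validated named list of class \code{"SimParams"}.
#' @export
SimParams <- function(seed = 1L, n_msih = 1L, n_mss = 1L,
        sample_type = c("fresh", "cell_line", "ffpe"),
        unstable_marker_rate = 0.6, stutter_rate = 0.05, shift_units = 3L,
        tumor_fraction = 0.35, coverage_mean = 100,
        coverage_dispersion = NULL, dropout_rate = NULL,
        ffpe_noise_rate = NULL) {
    sample_type <- match.arg(sample_type)
    ffpe <- sample_type == "ffpe"
    if (is.null(coverage_dispersion))
        coverage_dispersion <- if (ffpe) 0.2 else 0.02
    if (is.null(dropout_rate)) dropout_rate <- if (ffpe) 0.15 else 0
    if (is.null(ffpe_noise_rate)) ffpe_noise_rate <- if (ffpe) 0.05 else 0
    seed <- as.integer(seed)
    stopifnot(!is.na(seed))
    n_msih <- as.integer(n_msih); n_mss <- as.integer(n_mss)
    stopifnot(n_msih >= 0L, n_mss >= 0L, n_msih + n_mss >= 1L)
    .assertScalarNumber(unstable_marker_rate, "unstable_marker_rate",
        lower = 0, upper = 1, lower_open = TRUE)
    .assertScalarNumber(stutter_rate, "stutter_rate", 0, 0.5)
    shift_units <- as.integer(shift_units)
    if (is.na(shift_units) || shift_units == 0L)
        stop("'shift_units' must be a non-zero integer")
    .assertScalarNumber(tumor_fraction, "tumor_fraction", 0, 1,
        lower_open = TRUE)
    .assertScalarNumber(coverage_mean, "coverage_mean", 0, Inf,
        lower_open = TRUE)
    .assertScalarNumber(coverage_dispersion, "coverage_dispersion", 0, Inf,
        lower_open = TRUE)
    .assertScalarNumber(dropout_rate, "dropout_rate", 0, 1,
        upper_open = TRUE)
    .assertScalarNumber(ffpe_noise_rate, "ffpe_noise_rate", 0, 0.5)
    structure(list(seed = seed, n_msih = n_msih, n_mss = n_mss,
        sample_type = sample_type,
        unstable_marker_rate = unstable_marker_rate,
        stutter_rate = stutter_rate, shift_units = shift_units,
        tumor_fraction = tumor_fraction, coverage_mean = coverage_mean,
        coverage_dispersion = coverage_dispersion,
        dropout_rate = dropout_rate, ffpe_noise_rate = ffpe_noise_rate),
        class = "SimParams")
}

# Vectorized core: deltas for all markers of one sample, drawn from the
# current RNG state. truth_flags / ref_len / unit_len are parallel to the
# panel.
.simSampleDeltas <- function(truth_flags, ref_len, unit_len, p) {
    nm <- length(truth_flags)
    cov <- stats::rnbinom(nm, mu = p$coverage_mean,
                          size = 1 / p$coverage_dispersion)
    if (p$dropout_rate > 0) {
        drop <- stats::runif(nm) < p$dropout_rate
        cov[drop] <- sample(0:25, sum(drop), replace = TRUE)
    }
    total <- sum(cov)
    mi <- rep.int(seq_len(nm), cov)
    shifted <- truth_flags[mi] & (stats::runif(total) < p$tumor_fraction)
    d <- ifelse(shifted, -as.integer(p$shift_units) * unit_len[mi], 0L)
    slip <- stats::runif(total) < p$stutter_rate
    sgn <- sample(c(-1L, 1L), total, replace = TRUE)
    d <- d + ifelse(slip, sgn * unit_len[mi], 0L)
    if (p$ffpe_noise_rate > 0) {
        art <- stats::runif(total) < p$ffpe_noise_rate
        asgn <- sample(c(-1L, 1L), total, replace = TRUE)
        d <- d + ifelse(art, asgn, 0L)
    }
    d <- pmax(as.integer(d), -ref_len[mi])  # tract floor: zero bases
    IRanges::relist(d, IRanges::PartitioningByWidth(cov))
}

#' Simulate one marker's length distribution
#'
#' Draws a single marker's delta multiset under the stutter / contraction /
#' FFPE model of \code{\link{SimParams}}, from the \emph{current} RNG state
#' (seed it with \code{set.seed} or use \code{\link{simulateCohort}} for
#' seeded end-to-end generation). A stable marker emits delta 0 with
#' probability \code{1 - stutter_rate} and otherwise slips one repeat unit
#' either way; an unstable marker mixes that law (weight
#' \code{1 - tumor_fraction}) with a contracted allele at
#' \code{-shift_units * nchar(repeat_unit)} bp carrying its own stutter.
#'
#' @param unstable logical: does this marker carry the unstable allele?
#' @param ref_length reference tract length (bp).
#' @param repeat_unit repeat motif (its length sets the slip size).
#' @param params a \code{\link{SimParams}} list.
#' @return integer vector of deltas (length = simulated coverage).
#' @export
simulateMarker <- function(unstable, ref_length, repeat_unit, params) {
    stopifnot(inherits(params, "SimParams"))
    unlist(.simSampleDeltas(as.logical(unstable),
        as.integer(ref_length), nchar(repeat_unit), params),
        use.names = FALSE)
}

#' Simulate a cohort of MSI-H and MSS samples over a panel
#'
#' Generates \code{n_msih + n_mss} samples with recorded ground truth. In
#' each MSI-H sample a random subset of
#' \code{round(unstable_marker_rate * length(panel))} markers is marked
#' truth-unstable and receives the contracted-allele mixture; all other
#' markers (and every marker of MSS samples) follow the stable stutter
#' law. Identical \code{SimParams} (including seed) always reproduce the
#' identical cohort.
#'
#' @param panel a non-empty \linkS4class{MarkerPanel}.
#' @param params a \code{\link{SimParams}} list.
#' @return a \linkS4class{SimulatedCohort}.
#' @examples
#' p <- syntheticPanel(23, seed = 5)
#' simulateCohort(p, SimParams(seed = 1, n_msih = 2, n_mss = 3))
#' @export
simulateCohort <- function(panel, params) {
    stopifnot(methods::is(panel, "MarkerPanel"), length(panel) >= 1L,
              inherits(params, "SimParams"))
    ids <- markerIds(panel)
    rl <- unname(refLength(panel))
    ul <- unname(nchar(repeatUnit(panel)))
    sample_ids <- c(sprintf("msih_%03d", seq_len(params$n_msih)),
                    sprintf("mss_%03d", seq_len(params$n_mss)))
    truth <- stats::setNames(rep(c("MSI-H", "MSS"),
        c(params$n_msih, params$n_mss)), sample_ids)
    n_unst <- max(1L, round(params$unstable_marker_rate * length(panel)))
    tu <- matrix(FALSE, length(panel), length(sample_ids),
                 dimnames = list(ids, sample_ids))
    samples <- withSeed(params$seed, {
        lapply(sample_ids, function(sid) {
            flags <- rep(FALSE, length(panel))
            if (truth[[sid]] == "MSI-H")
                flags[sample.int(length(panel), n_unst)] <- TRUE
            tu[, sid] <<- flags
            d <- .simSampleDeltas(flags, rl, ul, params)
            names(d) <- ids
            LengthDistributions(d, sample_id = sid, ref_length = rl)
        })
    })
    names(samples) <- sample_ids
    methods::new("SimulatedCohort", params = unclass(params),
        panel = panel, samples = samples, truth = truth,
        truthUnstable = tu)
}

# Toy reference: random bases everywhere, the repeat motif inside each
# marker tract. Deterministic in `seed`.
.syntheticReference <- function(panel, seed) {
    gr <- markerRanges(panel)
    chroms <- GenomeInfoDb::seqlevels(gr)
    withSeed(seed, {
        seqs <- lapply(chroms, function(ch) {
            on_ch <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
            len <- max(GenomicRanges::end(on_ch)) + 200L
            s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
            for (i in seq_along(on_ch)) {
                w <- GenomicRanges::width(on_ch)[i]
                ru <- strsplit(S4Vectors::mcols(on_ch)$repeat_unit[i],
                               "")[[1L]]
                s[GenomicRanges::start(on_ch)[i]:GenomicRanges::end(on_ch)[i]] <-
                    rep_len(ru, w)
            }
            paste(s, collapse = "")
        })
        names(seqs) <- chroms
        Biostrings::DNAStringSet(unlist(seqs))
    })
}

.readForDelta <- function(ref, start0, end0, delta, unit, flank_bp = 55L) {
    rl <- end0 - start0
    left0 <- start0 - flank_bp           # 0-based read start
    if (delta == 0L) {
        list(pos = left0 + 1L,
             cigar = sprintf("%dM", 2L * flank_bp + rl),
             seq = substr(ref, left0 + 1L, end0 + flank_bp))
    } else if (delta > 0L) {
        cut <- rl %/% 2L                 # insertion strictly inside tract
        ins <- substr(strrep(unit, ceiling(delta / nchar(unit))), 1L, delta)
        list(pos = left0 + 1L,
             cigar = sprintf("%dM%dI%dM", flank_bp + cut, delta,
                             rl - cut + flank_bp),
             seq = paste0(substr(ref, left0 + 1L, start0 + cut), ins,
                          substr(ref, start0 + cut + 1L, end0 + flank_bp)))
    } else {
        stopifnot(delta >= -rl)
        list(pos = left0 + 1L,
             cigar = sprintf("%dM%dD%dM", flank_bp + rl + delta, -delta,
                             flank_bp),
             seq = paste0(substr(ref, left0 + 1L, end0 + delta),
                          substr(ref, end0 + 1L, end0 + flank_bp)))
    }
}

#' Emit a simulated cohort as toy reference FASTA plus per-sample SAM
#'
#' Materializes every simulated delta as one single-end spanning read whose
#' CIGAR encodes the corresponding insertion or deletion inside the marker
#' tract (55 bp anchored flank on each side), over a deterministic toy
#' reference in which each marker tract is its repeat motif. This is the
#' end-to-end test surface for the extraction code: collecting length
#' distributions from the emitted SAM must reproduce the cohort's delta
#' multisets exactly. No timestamps are written, so identical cohorts emit
#' byte-identical files.
#'
#' @param cohort a \linkS4class{SimulatedCohort} generated on a panel with
#'   compact toy coordinates (e.g. \code{\link{syntheticPanel}}); every
#'   marker needs at least 60 bp clearance from its neighbours and the
#'   chromosome start, and chromosomes must stay small (< 5 Mb).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named list of written paths: \code{reference}
#'   (FASTA), \code{sam} (one per sample), \code{truth_samples},
#'   \code{truth_markers}, \code{truth_reads} (TSVs).
#' @export
emitSam <- function(cohort, out_dir) {
    stopifnot(methods::is(cohort, "SimulatedCohort"))
    panel <- cohort@panel
    gr <- markerRanges(panel)
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (any(start0 < 60L))
        stop("marker too close to chromosome start for flanked reads")
    gaps <- unlist(lapply(split(seq_along(gr), chrom), function(i)
        if (length(i) > 1L) start0[i][-1L] - end0[i][-length(i)] else
            integer()))
    if (length(gaps) && min(gaps) < 150L)
        stop("markers closer than 150 bp: reads would span neighbours")
    ref <- .syntheticReference(panel, seed = cohort@params$seed + 7L)
    if (sum(Biostrings::width(ref)) > 5e6)
        stop("toy reference would exceed 5 Mb; use a compact panel")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ref_path <- file.path(out_dir, "reference.fa")
    Biostrings::writeXStringSet(ref, ref_path)
    refc <- as.character(ref)
    units <- unname(repeatUnit(panel))
    ids <- markerIds(panel)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref),
                     Biostrings::width(ref)),
             "@PG\tID:msiskew\tPN:msiskew-simulate")
    sam_paths <- character(0)
    truth_reads <- list()
    for (sid in names(cohortSamples(cohort))) {
        d <- deltas(cohortSamples(cohort)[[sid]])
        recs <- character(0)
        tr <- list()
        for (i in seq_along(gr)) {
            dv <- d[[ids[i]]]
            if (!length(dv)) next
            rows <- vapply(seq_along(dv), function(k) {
                rd <- .readForDelta(refc[[chrom[i]]], start0[i], end0[i],
                                    dv[k], units[i])
                sprintf("%s:%s:%04d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    sid, ids[i], k, chrom[i], rd$pos, rd$cigar, rd$seq,
                    strrep("I", nchar(rd$seq)))
            }, character(1L))
            recs <- c(recs, rows)
            tr[[ids[i]]] <- data.frame(sample_id = sid,
                qname = sprintf("%s:%s:%04d", sid, ids[i],
                                seq_along(dv)),
                marker_id = ids[i], delta = dv)
        }
        p <- file.path(out_dir, paste0(sid, ".sam"))
        writeLines(c(hdr, recs), p)
        sam_paths <- c(sam_paths, p)
        truth_reads <- c(truth_reads, tr)
    }
    ts_path <- file.path(out_dir, "truth_samples.tsv")
    utils::write.table(data.frame(sample_id = names(truthStatus(cohort)),
        truth_status = unname(truthStatus(cohort))), ts_path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    tu <- truthUnstable(cohort)
    tm_path <- file.path(out_dir, "truth_markers.tsv")
    utils::write.table(data.frame(
        sample_id = rep(colnames(tu), each = nrow(tu)),
        marker_id = rep(rownames(tu), ncol(tu)),
        truth_unstable = as.vector(tu)), tm_path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    tr_path <- file.path(out_dir, "truth_reads.tsv")
    utils::write.table(do.call(rbind, truth_reads), tr_path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(list(reference = ref_path, sam = sam_paths,
        truth_samples = ts_path, truth_markers = tm_path,
        truth_reads = tr_path))
}
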