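#' @include AllClasses.R AllGenerics.R
NULL

.parseCigar <- function(cigar) {
    if (is.na(cigar) || identical(cigar, "*")) return(NULL)
    pat <- "\\d+[MIDNSHP=X]"
    toks <- regmatches(cigar, gregexpr(pat, cigar))[[1L]]
    if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) return(NULL)
    list(op = substring(toks, nchar(toks)),
         len = as.integer(sub(".$", "", toks)))
}

#' Microsatellite tract length of one aligned read
#'
#' Measures the repeat-tract length a read reports at a marker by a single
#' walk over its CIGAR. The read must span the marker plus \code{flank}
#' anchor bases on both sides with aligned (M/=/X) or deleted (D) reference
#' bases -- a reference skip (N) inside the window, or an alignment that
#' starts or ends inside it (clipped tails included), disqualifies the read.
#' The tract length is then the reference tract length, plus query bases
#' inserted at reference breakpoints strictly inside the marker interval,
#' minus reference bases deleted within it. Insertions exactly at the
#' marker boundaries belong to the flank, not the tract; deletions are
#' counted by closed-open overlap with the marker interval.
#'
#' @param pos 1-based leftmost aligned reference position (SAM POS).
#' @param cigar CIGAR string.
#' @param start,end marker interval, 0-based half-open.
#' @param flank anchor bases required on each side of the marker
#'   (default 5).
#' @return integer tract length in bp, or \code{NA} if the read does not
#'   span the window or the CIGAR is unusable.
#' @examples
#' tractLength(1, "100M", start = 30, end = 56)        # 26: reference length
#' tractLength(1, "50M2D48M", start = 30, end = 56)    # 24: 2 bp deleted
#' @export
tractLength <- function(pos, cigar, start, end, flank = 5L) {
    cg <- .parseCigar(cigar)
    if (is.null(cg)) return(NA_integer_)
    ws <- start - flank
    we <- end + flank
    r <- pos - 1L          # 0-based reference cursor
    inserted <- 0L
    deleted <- 0L
    span_start <- r
    for (k in seq_along(cg$op)) {
        op <- cg$op[k]
        len <- cg$len[k]
        if (op %in% c("M", "=", "X", "D", "N")) {
            if (op == "N" && r < we && r + len > ws)
                return(NA_integer_)  # splice through the window
            if (op == "D") {
                ov <- min(r + len, end) - max(r, start)
                if (ov > 0L) deleted <- deleted + ov
            }
            r <- r + len
        } else if (op == "I") {
            if (r > start && r < end) inserted <- inserted + len
        }
        # S/H/P consume no reference
    }
    if (span_start > ws || r < we) return(NA_integer_)
    (end - start) + inserted - deleted
}

.samFlagKeep <- function(flag) {
    drop <- bitwAnd(flag, 0x4L) > 0L |    # unmapped
        bitwAnd(flag, 0x100L) > 0L |      # secondary
        bitwAnd(flag, 0x200L) > 0L |      # QC fail
        bitwAnd(flag, 0x400L) > 0L |      # duplicate
        bitwAnd(flag, 0x800L) > 0L        # supplementary
    !drop
}

# Minimal SAM reader: mandatory fields needed for tract-length extraction.
.readSamRecords <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "@")]
    sq <- hdr[startsWith(hdr, "@SQ")]
    seqs <- vapply(strsplit(sq, "\t", fixed = TRUE), function(f) {
        sn <- f[startsWith(f, "SN:")]
        if (length(sn)) sub("^SN:", "", sn[1L]) else NA_character_
    }, character(1L))
    body <- lines[!startsWith(lines, "@")]
    body <- body[nzchar(body)]
    if (!length(body))
        return(list(seqnames = seqs, reads = data.frame(
            qname = character(), flag = integer(), rname = character(),
            pos = integer(), mapq = integer(), cigar = character())))
    f <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 11L)
    if (length(bad))
        stop(sprintf("malformed SAM record at line %d",
                     which(!startsWith(lines, "@"))[bad[1L]]))
    reads <- data.frame(
        qname = vapply(f, `[[`, "", 1L),
        flag = as.integer(vapply(f, `[[`, "", 2L)),
        rname = vapply(f, `[[`, "", 3L),
        pos = as.integer(vapply(f, `[[`, "", 4L)),
        mapq = as.integer(vapply(f, `[[`, "", 5L)),
        cigar = vapply(f, `[[`, "", 6L),
        stringsAsFactors = FALSE)
    list(seqnames = seqs, reads = reads)
}

.readBamRecords <- function(path) {
    hdr <- Rsamtools::scanBamHeader(path)[[1L]]
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
            isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
            isDuplicate = FALSE, isNotPassingQualityControls = FALSE))
    b <- Rsamtools::scanBam(path, param = param)[[1L]]
    list(seqnames = names(hdr$targets), reads = data.frame(
        qname = b$qname, flag = b$flag, rname = as.character(b$rname),
        pos = b$pos, mapq = b$mapq, cigar = b$cigar,
        stringsAsFactors = FALSE))
}

#' Collect per-marker length distributions from aligned reads
#'
#' Runs \code{\link{tractLength}} for every read over every marker it spans
#' and assembles per-marker multisets of normalized deltas (tract length
#' minus reference tract length). Reads flagged unmapped, secondary,
#' supplementary, duplicate or QC-fail are excluded, as are reads below the
#' mapping-quality floor; each read contributes at most one delta per
#' marker. A panel chromosome missing from the alignment header yields
#' coverage 0 for its markers, with a warning.
#'
#' @param path SAM (text) or BAM file of one coordinate-sorted tumor sample.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param flank anchor bases required on each side of a marker (default 5).
#' @param mapq_min minimum mapping quality (default 20).
#' @param sample_id sample name for the result (default: file base name).
#' @return a \linkS4class{LengthDistributions} with one element per panel
#'   marker, in panel order.
#' @export
collectLengthDistributions <- function(path, panel, flank = 5L,
        mapq_min = 20L,
        sample_id = sub("\\.(sam|bam)$", "", basename(path))) {
    stopifnot(methods::is(panel, "MarkerPanel"))
    src <- if (grepl("\\.bam$", path, ignore.case = TRUE))
        .readBamRecords(path) else .readSamRecords(path)
    reads <- src$reads
    keep <- .samFlagKeep(reads$flag) & !is.na(reads$pos) &
        reads$mapq >= mapq_min & reads$cigar != "*"
    reads <- reads[keep, , drop = FALSE]
    gr <- markerRanges(panel)
    ids <- markerIds(panel)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    missing_chr <- setdiff(unique(chrom), src$seqnames)
    if (length(missing_chr))
        warning("panel chromosome(s) absent from alignment header: ",
                paste(missing_chr, collapse = ", "),
                "; affected markers get coverage 0")
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    out <- vector("list", length(gr))
    for (i in seq_along(gr)) {
        if (chrom[i] %in% missing_chr || !nrow(reads)) {
            out[[i]] <- integer()
            next
        }
        ws <- start0[i] - flank
        we <- end0[i] + flank
        cand <- which(reads$rname == chrom[i] & reads$pos <= ws + 1L &
                      reads$pos + 1e4L >= we)
        if (!length(cand)) {
            out[[i]] <- integer()
            next
        }
        tl <- vapply(cand, function(j) tractLength(reads$pos[j],
            reads$cigar[j], start0[i], end0[i], flank), integer(1L))
        # one delta per read per marker (mates keep distinct flags)
        key <- paste(reads$qname[cand], reads$flag[cand])
        ok <- !is.na(tl) & !duplicated(key)
        out[[i]] <- unname(tl[ok]) - (end0[i] - start0[i])
    }
    names(out) <- ids
    LengthDistributions(out, sample_id = sample_id,
                        ref_length = unname(refLength(panel)))
}

#' Write / read a per-marker length table
#'
#' The length table is the TSV interchange format between extraction and
#' scoring: one row per marker with columns marker_id, coverage and the
#' comma-separated sorted deltas. It is accepted anywhere a BAM is, so the
#' statistical pipeline can run without alignments.
#'
#' @param x a \linkS4class{LengthDistributions}.
#' @param path file path.
#' @return \code{writeLengthTable} invisibly returns \code{path};
#'   \code{readLengthTable} returns a \linkS4class{LengthDistributions}.
#' @export
writeLengthTable <- function(x, path) {
    stopifnot(methods::is(x, "LengthDistributions"))
    d <- deltas(x)
    rows <- sprintf("%s\t%d\t%s", names(d), lengths(d),
        vapply(d, function(v) paste(sort(v), collapse = ","), character(1L)))
    writeLines(c(sprintf("# msiskew length table: %s", sampleId(x)),
                 "# marker_id\tcoverage\tdeltas", rows), path)
    invisible(path)
}

#' @rdname writeLengthTable
#' @param panel optional \linkS4class{MarkerPanel} supplying reference tract
#'   lengths (enables the no-negative-tract validity check) and the marker
#'   order; markers absent from the table get coverage 0.
#' @param sample_id sample name; defaults to the header comment or the file
#'   base name.
#' @export
readLengthTable <- function(path, panel = NULL, sample_id = NULL) {
    lines <- readLines(path)
    if (is.null(sample_id)) {
        m <- regmatches(lines, regexpr("(?<=length table: ).+", lines,
                                       perl = TRUE))
        sample_id <- if (length(m)) trimws(m[[1L]]) else
            sub("\\.[^.]*$", "", basename(path))
    }
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(f, `[[`, "", 1L)
    dl <- lapply(f, function(x) {
        if (length(x) < 3L || !nzchar(x[3L])) integer() else
            as.integer(strsplit(x[3L], ",", fixed = TRUE)[[1L]])
    })
    cov <- as.integer(vapply(f, `[[`, "", 2L))
    if (!all(cov == lengths(dl)))
        stop("length table corrupt: coverage column disagrees with deltas")
    names(dl) <- ids
    rl <- NA_integer_
    if (!is.null(panel)) {
        extra <- setdiff(ids, markerIds(panel))
        if (length(extra))
            stop("length table has markers not in panel: ",
                 paste(extra, collapse = ", "))
        full <- stats::setNames(
            rep(list(integer()), length(panel)), markerIds(panel))
        full[ids] <- dl
        dl <- full
        rl <- unname(refLength(panel))
    }
    LengthDistributions(dl, sample_id = sample_id, ref_length = rl)
}
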