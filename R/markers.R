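#' @include AllClasses.R AllGenerics.R
NULL

.panelGRanges <- function(chrom, start0, end0, marker_id, repeat_unit) {
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1L, end = end0),
        marker_id = as.character(marker_id),
        repeat_unit = toupper(as.character(repeat_unit)))
}

#' Read a microsatellite marker panel from a TSV file
#'
#' The panel format is a BED-compatible tab-separated file with six columns:
#' chrom, start (0-based), end (exclusive), marker_id, repeat_unit,
#' ref_length. Lines starting with \code{#} are comments; a comment of the
#' form \code{# panel: NAME} sets the panel name.
#'
#' @param path path to the panel file.
#' @param name optional panel name overriding the header comment.
#' @return a validated \linkS4class{MarkerPanel}.
#' @examples
#' p <- readMarkerPanel(system.file("extdata", "panel23.tsv",
#'                                  package = "msiskew"))
#' length(p)
#' @export
readMarkerPanel <- function(path, name = NULL) {
    if (!file.exists(path)) stop("panel file not found: ", path)
    lines <- readLines(path)
    is_comment <- startsWith(lines, "#")
    if (is.null(name)) {
        m <- regmatches(lines[is_comment],
                        regexpr("(?<=panel: ).+", lines[is_comment],
                                perl = TRUE))
        name <- if (length(m)) trimws(m[[1L]]) else
            sub("\\.[^.]*$", "", basename(path))
    }
    keep <- which(!is_comment & nzchar(trimws(lines)))
    if (!length(keep))
        return(MarkerPanel(.panelGRanges(character(), integer(), integer(),
            character(), character()), name = name))
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 6L))
        stop(sprintf("malformed panel line %d: expected 6 tab-separated fields, got %d",
            keep[which(nf != 6L)[1L]], nf[nf != 6L][1L]))
    tab <- do.call(rbind, fields)
    start0 <- suppressWarnings(as.integer(tab[, 2L]))
    end0 <- suppressWarnings(as.integer(tab[, 3L]))
    rl <- suppressWarnings(as.integer(tab[, 6L]))
    bad <- which(is.na(start0) | is.na(end0) | is.na(rl))
    if (length(bad))
        stop(sprintf("malformed panel line %d: non-integer coordinate or length",
            keep[bad[1L]]))
    if (any(end0 <= start0))
        stop(sprintf("invalid marker at line %d: end must exceed start",
            keep[which(end0 <= start0)[1L]]))
    mismatch <- which(rl != end0 - start0)
    if (length(mismatch))
        stop(sprintf(
            "invalid marker '%s' (line %d): ref_length %d != end - start = %d",
            tab[mismatch[1L], 4L], keep[mismatch[1L]], rl[mismatch[1L]],
            (end0 - start0)[mismatch[1L]]))
    MarkerPanel(.panelGRanges(tab[, 1L], start0, end0, tab[, 4L],
                              tab[, 5L]), name = name)
}

#' Write a marker panel to a TSV file
#'
#' Inverse of \code{\link{readMarkerPanel}}: coordinates are written 0-based
#' half-open, with a header comment recording the panel name.
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMarkerPanel <- function(panel, path) {
    stopifnot(methods::is(panel, "MarkerPanel"))
    methods::validObject(panel)
    gr <- markerRanges(panel)
    header <- c(sprintf("# msiskew marker panel: %s", panelName(panel)),
                "# chrom\tstart\tend\tmarker_id\trepeat_unit\tref_length")
    rows <- if (length(gr)) sprintf("%s\t%d\t%d\t%s\t%s\t%d",
        as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
        markerIds(panel), repeatUnit(panel), GenomicRanges::width(gr))
        else character()
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Draw a random marker subset from a panel
#'
#' Samples \code{n} markers uniformly without replacement, reproducibly from
#' \code{seed}; the result is coordinate-sorted. Used to derive
#' intermediate-sized panels from a large candidate panel.
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @param n number of markers to keep (\code{n <= length(panel)}).
#' @param seed integer seed; identical (panel, n, seed) always returns the
#'   identical subset.
#' @param name name for the derived panel.
#' @return a \linkS4class{MarkerPanel} of \code{n} markers.
#' @export
subsetPanel <- function(panel, n, seed,
                        name = sprintf("%s_sub%d", panelName(panel), n)) {
    stopifnot(methods::is(panel, "MarkerPanel"))
    n <- as.integer(n)
    if (is.na(n) || n < 1L || n > length(panel))
        stop(sprintf("'n' must be in [1, %d], got %s", length(panel),
                     format(n)))
    idx <- withSeed(seed, sample.int(length(panel), n))
    out <- panel[sort(idx)]
    out@panelName <- name
    methods::validObject(out)
    out
}

#' Generate a synthetic candidate marker panel on toy chromosomes
#'
#' Places \code{n} microsatellite loci on a small set of toy chromosomes
#' with wide unique flanks (minimum gap 250 bp), mixing A/T homopolymers
#' (the dominant class in coding regions) with di- and trinucleotide
#' repeats. Tract lengths are 12-30 bp for mononucleotide and 4-10 repeat
#' units otherwise. Coordinates are compact so a matching toy reference
#' genome stays small; see \code{\link{emitSam}}.
#'
#' @param n number of markers.
#' @param seed integer seed; generation is fully reproducible.
#' @param n_chrom number of toy chromosomes to spread markers over.
#' @param name panel name.
#' @return a \linkS4class{MarkerPanel}.
#' @examples
#' syntheticPanel(50, seed = 1)
#' @export
syntheticPanel <- function(n, seed, n_chrom = 4L,
                           name = sprintf("synthetic%d", n)) {
    n <- as.integer(n)
    stopifnot(n >= 1L)
    withSeed(seed, {
        units <- c("A", "T", "AC", "AG", "AT", "AAG", "ATC")
        prob <- c(0.35, 0.25, 0.12, 0.08, 0.08, 0.06, 0.06)
        ru <- sample(units, n, replace = TRUE, prob = prob)
        ulen <- nchar(ru)
        reps <- ifelse(ulen == 1L, sample(12:30, n, replace = TRUE),
                       sample(4:10, n, replace = TRUE))
        rl <- ulen * reps
        chrom <- sort(sample(sprintf("msim_chr%d", seq_len(n_chrom)), n,
                             replace = TRUE))
        gaps <- sample(250:600, n, replace = TRUE)
        start0 <- integer(n)
        pos <- stats::setNames(rep(200L, n_chrom),
                               sprintf("msim_chr%d", seq_len(n_chrom)))
        for (i in seq_len(n)) {
            start0[i] <- pos[[chrom[i]]]
            pos[[chrom[i]]] <- start0[i] + rl[i] + gaps[i]
        }
        MarkerPanel(.panelGRanges(chrom, start0, start0 + rl,
            sprintf("MS%04d", seq_len(n)), ru), name = name)
    })
}
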