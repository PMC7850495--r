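# Marker used throughout: 26 bp tract at 0-based [30, 56).

test_that("tract length equals reference length for indel-free spanning reads", {
    expect_equal(tractLength(1, "100M", 30, 56), 26L)
    # 2 bp deletion inside the tract shortens it
    expect_equal(tractLength(1, "50M2D48M", 30, 56), 24L)
    # insertion strictly inside the tract lengthens it
    expect_equal(tractLength(1, "40M3I60M", 30, 56), 29L)
})

test_that("non-spanning, clipped and skipped reads are rejected", {
    # alignment ends 3 bp past marker end: flank 5 not covered
    expect_equal(tractLength(1, "58M", 30, 56), NA_integer_)
    # starts inside the left flank window
    expect_equal(tractLength(28, "100M", 30, 56), NA_integer_)
    # soft clip shifts the aligned span out of the window
    expect_equal(tractLength(28, "10S90M", 30, 56), NA_integer_)
    # splice (N) through the window disqualifies
    expect_equal(tractLength(1, "40M10N50M", 30, 56), NA_integer_)
    # unusable CIGAR
    expect_equal(tractLength(1, "*", 30, 56), NA_integer_)
    # a leading soft clip outside the window is fine
    expect_equal(tractLength(11, "5S90M", 30, 56), 26L)
})

test_that("boundary insertions belong to the flank, interior deletions to the tract", {
    # insertion at reference breakpoint exactly marker.start: flank
    expect_equal(tractLength(1, "30M4I70M", 30, 56), 26L)
    # ... and exactly at marker.end: flank
    expect_equal(tractLength(1, "56M4I44M", 30, 56), 26L)
    # one base further in: tract
    expect_equal(tractLength(1, "31M4I69M", 30, 56), 30L)
    # deletion straddling the marker start counts only its overlap
    expect_equal(tractLength(1, "28M4D68M", 30, 56), 24L)
    # deletion of the entire tract
    expect_equal(tractLength(1, "30M26D30M", 30, 56), 0L)
})

test_that("the CIGAR walk agrees with the per-base coordinate-map oracle", {
    set.seed(424242)
    n_agree <- 0L
    for (i in 1:400) {
        rd <- random_alignment(30, 56)
        got <- tractLength(rd$pos, rd$cigar, 30, 56)
        want <- tract_oracle(rd$pos, rd$cigar, 30, 56)
        expect_identical(got, want,
            info = sprintf("pos=%d cigar=%s", rd$pos, rd$cigar))
        if (!is.na(got)) n_agree <- n_agree + 1L
    }
    expect_gt(n_agree, 20L)  # the case mix includes real spanning reads
})

test_that("collection from SAM honors filters and marker assignment", {
    sam <- withr::local_tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:1000")
    seq100 <- strrep("A", 100)
    q <- strrep("I", 100)
    rec <- function(name, flag, pos, mapq, cigar, seq = seq100, qq = q)
        sprintf("%s\t%d\tchr1\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                name, flag, pos, mapq, cigar, seq, qq)
    pf <- withr::local_tempfile(fileext = ".tsv")
    writeLines("chr1\t30\t56\tM1\tA\t26", pf)
    panel <- readMarkerPanel(pf)

    # empty file: coverage 0 everywhere
    writeLines(hdr, sam)
    x <- collectLengthDistributions(sam, panel)
    expect_identical(unname(markerCoverage(x)), 0L)

    # 30 clean spanning reads -> thirty zero deltas
    writeLines(c(hdr, vapply(1:30, function(i)
        rec(sprintf("r%02d", i), 0L, 1L, 60L, "100M"), character(1))), sam)
    x <- collectLengthDistributions(sam, panel)
    expect_identical(deltas(x)[["M1"]], rep(0L, 30))

    # duplicates, secondary, low-mapq and non-spanning reads change nothing
    extra <- c(rec("dup", 1024L, 1L, 60L, "100M"),
               rec("sec", 256L, 1L, 60L, "100M"),
               rec("lowq", 0L, 1L, 5L, "100M"),
               rec("short", 0L, 40L, 60L, "100M"),
               rec("r01", 0L, 1L, 60L, "50M2D48M"))  # same qname+flag again
    writeLines(c(hdr, vapply(1:30, function(i)
        rec(sprintf("r%02d", i), 0L, 1L, 60L, "100M"), character(1)),
        extra), sam)
    y <- collectLengthDistributions(sam, panel)
    expect_identical(deltas(y)[["M1"]], deltas(x)[["M1"]])

    # a panel chromosome missing from the header warns, coverage 0
    pf2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chr1\t30\t56\tM1\tA\t26", "chr9\t30\t56\tM2\tA\t26"), pf2)
    p2 <- readMarkerPanel(pf2)
    expect_warning(z <- collectLengthDistributions(sam, p2),
                   "chr9")
    expect_identical(unname(markerCoverage(z)), c(30L, 0L))
})

test_that("length tables round-trip through TSV", {
    p <- syntheticPanel(8, seed = 21)
    co <- simulateCohort(p, SimParams(seed = 3, n_msih = 1, n_mss = 0))
    s <- cohortSamples(co)[[1L]]
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLengthTable(s, f)
    r <- readLengthTable(f, panel = p)
    expect_identical(sampleId(r), sampleId(s))
    expect_identical(lapply(deltas(r), sort),
                     lapply(as.list(deltas(s)), sort))
    # without a panel the table stands alone
    r2 <- readLengthTable(f)
    expect_identical(unname(markerCoverage(r2)),
                     unname(markerCoverage(s)))
})
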