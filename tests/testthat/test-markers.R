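test_that("a single well-formed record parses into a one-marker panel", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines("chr2\t10\t36\tBAT26\tA\t26", f)
    p <- readMarkerPanel(f)
    expect_s4_class(p, "MarkerPanel")
    expect_equal(length(p), 1L)
    expect_equal(unname(refLength(p)), 26L)
    expect_equal(markerIds(p), "BAT26")
    expect_equal(GenomicRanges::start(markerRanges(p)), 11L)  # 1-based
})

test_that("panel validation rejects malformed and inconsistent records", {
    f <- withr::local_tempfile(fileext = ".tsv")
    # duplicate id
    writeLines(c("chr1\t10\t20\tM1\tA\t10", "chr2\t10\t20\tM1\tA\t10"), f)
    expect_error(readMarkerPanel(f), "duplicate marker_id")
    # overlap on the same chromosome
    writeLines(c("chr1\t10\t20\tM1\tA\t10", "chr1\t15\t25\tM2\tA\t10"), f)
    expect_error(readMarkerPanel(f), "overlap")
    # identical coordinates, different ids
    writeLines(c("chr1\t10\t20\tM1\tA\t10", "chr1\t10\t20\tM2\tA\t10"), f)
    expect_error(readMarkerPanel(f), "overlap")
    # ref_length inconsistent with the interval
    writeLines("chr1\t10\t20\tM1\tA\t11", f)
    expect_error(readMarkerPanel(f), "ref_length 11 != end - start = 10")
    # wrong field count names the line
    writeLines(c("chr1\t10\t20\tM1\tA\t10", "chr1\t30\t40\tM2\tA"), f)
    expect_error(readMarkerPanel(f), "line 2")
    # bad motif alphabet / length
    writeLines("chr1\t10\t20\tM1\tAN\t10", f)
    expect_error(readMarkerPanel(f), "repeat_unit")
    writeLines("chr1\t10\t20\tM1\tAAAAAAA\t10", f)
    expect_error(readMarkerPanel(f), "repeat_unit")
    # end <= start
    writeLines("chr1\t20\t20\tM1\tA\t0", f)
    expect_error(readMarkerPanel(f), "end must exceed start")
})

test_that("write/read round trip is the identity on valid panels", {
    f <- withr::local_tempfile(fileext = ".tsv")
    # empty panel -> header only, re-reads as empty
    empty <- MarkerPanel(markerRanges(syntheticPanel(1, 1))[0],
                         name = "empty")
    writeMarkerPanel(empty, f)
    expect_equal(length(readMarkerPanel(f)), 0L)
    expect_true(all(startsWith(readLines(f), "#")))
    for (seed in c(2, 11, 37)) {
        p <- syntheticPanel(sample(1:80, 1), seed = seed)
        writeMarkerPanel(p, f)
        q <- readMarkerPanel(f)
        expect_identical(markerIds(q), markerIds(p))
        expect_identical(refLength(q), refLength(p))
        expect_identical(repeatUnit(q), repeatUnit(p))
        expect_equal(panelName(q), panelName(p))
        expect_true(all(markerRanges(q) == markerRanges(p)))
    }
})

test_that("the packaged small panel holds exactly 23 markers", {
    p <- readMarkerPanel(panel23_path())
    expect_equal(length(p), 23L)
    expect_true(all(c("BAT25", "BAT26") %in% markerIds(p)))
    expect_true(validObject(p))
})

test_that("subsetPanel is deterministic in its seed and size-checked", {
    p <- syntheticPanel(40, seed = 9)
    s1 <- subsetPanel(p, 1, seed = 7)
    s2 <- subsetPanel(p, 1, seed = 7)
    expect_identical(markerIds(s1), markerIds(s2))
    full <- subsetPanel(p, length(p), seed = 3)
    expect_setequal(markerIds(full), markerIds(p))
    expect_error(subsetPanel(p, 41, seed = 1), "must be in \\[1, 40\\]")
    big <- subsetPanel(p, 25, seed = 5)
    expect_equal(length(big), 25L)
    o <- order(as.character(GenomicRanges::seqnames(markerRanges(big))),
               GenomicRanges::start(markerRanges(big)))
    expect_identical(o, seq_len(25L))  # coordinate-sorted output
})

test_that("subsetPanel draws uniformly over subsets", {
    p <- syntheticPanel(4, seed = 13)
    pairs <- vapply(1:1000, function(i)
        paste(sort(markerIds(subsetPanel(p, 2, seed = i))),
              collapse = "+"), character(1L))
    freq <- table(pairs) / 1000
    expect_equal(length(freq), choose(4, 2))
    se <- sqrt((1 / 6) * (5 / 6) / 1000)
    expect_true(all(abs(freq - 1 / 6) < 3 * se))
    # chi-square goodness of fit against the uniform law on 6 pairs
    chi <- sum((table(pairs) - 1000 / 6)^2 / (1000 / 6))
    expect_gt(stats::pchisq(chi, df = 5, lower.tail = FALSE), 0.001)
})
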