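mk <- function(...) c(...)

test_that("confusion counts and screening metrics are exact", {
    tr <- c(s1 = "MSI-H", s2 = "MSI-H", s3 = "MSI-H", s4 = "MSI-H",
            s5 = "MSS", s6 = "MSS", s7 = "MSS", s8 = "MSS", s9 = "MSS",
            s10 = "MSS")
    perfect <- msiConfusion(tr, tr)
    expect_equal(perfect[c("sensitivity", "specificity", "accuracy")],
                 list(sensitivity = 1, specificity = 1, accuracy = 1))
    # one of eight MSS miscalled: specificity 7/8
    tr8 <- setNames(rep("MSS", 8), paste0("c", 1:8))
    called8 <- tr8; called8["c3"] <- "MSI-H"
    expect_equal(msiConfusion(tr8, called8)$specificity, 0.875)
    # mixed errors
    tr4 <- c(a = "MSI-H", b = "MSI-H", c = "MSS", d = "MSS")
    ca <- c(a = "MSI-H", b = "MSS", c = "MSS", d = "MSS")
    cf <- msiConfusion(tr4, ca)
    expect_equal(cf[c("tp", "fn", "tn", "fp")],
                 list(tp = 1L, fn = 1L, tn = 2L, fp = 0L))
    expect_equal(cf$sensitivity, 0.5)
    expect_equal(cf$specificity, 1)
    expect_equal(cf$accuracy, 0.75)
})

test_that("confusion is permutation-invariant and handles edge inputs", {
    tr <- c(a = "MSI-H", b = "MSS", c = "MSS", d = "MSI-H")
    ca <- c(a = "MSI-H", b = "MSI-H", c = "MSS", d = "MSS")
    shuffled <- msiConfusion(tr[c(3, 1, 4, 2)], ca[c(2, 4, 1, 3)])
    expect_equal(shuffled, msiConfusion(tr, ca))
    # indeterminate calls are excluded, not counted as wrong
    ci <- ca; ci["b"] <- "indeterminate"
    expect_message(cf <- msiConfusion(tr, ci), "1 indeterminate")
    expect_equal(cf$n_indeterminate, 1L)
    expect_equal(cf$fp, 0L)
    # all-positive truth: specificity undefined, reported NA
    trp <- c(x = "MSI-H", y = "MSI-H")
    cap <- c(x = "MSI-H", y = "MSS")
    expect_true(is.na(msiConfusion(trp, cap)$specificity))
    expect_error(msiConfusion(tr, ca[1:3]), "identical sample set")
})

test_that("McNemar p-values match closed forms on both branches", {
    tr <- setNames(rep("MSI-H", 30), sprintf("s%02d", 1:30))
    agree <- tr
    r0 <- mcnemarPaired(agree, agree, tr)
    expect_equal(r0$b + r0$c, 0L)
    expect_equal(r0$p.value, 1)
    # b = 5, c = 0: exact two-sided binomial, p = 2 * (1/2)^5
    a5 <- tr; b5 <- tr
    b5[1:5] <- "MSS"
    r5 <- mcnemarPaired(a5, b5, tr)
    expect_equal(c(r5$b, r5$c), c(5L, 0L))
    expect_equal(r5$method, "exact-binomial")
    expect_equal(r5$p.value, 2 * 0.5^5, tolerance = 1e-12)
    # b = 20, c = 5: continuity-corrected chi-square (14^2)/25 = 7.84
    tr25 <- setNames(rep("MSI-H", 25), sprintf("t%02d", 1:25))
    aa <- tr25; bb <- tr25
    bb[1:20] <- "MSS"     # A right, B wrong on 20
    aa[21:25] <- "MSS"    # B right, A wrong on 5
    r25 <- mcnemarPaired(aa, bb, tr25)
    expect_equal(c(r25$b, r25$c), c(20L, 5L))
    expect_equal(r25$method, "chi-square")
    expect_equal(r25$p.value, stats::pchisq(7.84, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("exact branch equals brute-force binomial enumeration", {
    # two-sided exact test: sum of P(X = k) over k with P <= P(observed)
    enum_p <- function(b, n) {
        probs <- vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1))
        sum(probs[probs <= probs[b + 1L] + 1e-12])
    }
    for (n in c(1, 2, 5, 8, 12)) for (b in 0:n) {
        tr <- setNames(rep("MSI-H", n + 10L), sprintf("q%02d", seq_len(n + 10L)))
        ca <- tr; cb <- tr
        if (b > 0) cb[seq_len(b)] <- "MSS"
        if (b < n) ca[(b + 1L):n] <- "MSS"
        r <- mcnemarPaired(ca, cb, tr)
        expect_equal(c(r$b, r$c), c(b, n - b))
        expect_equal(r$p.value, enum_p(b, n), tolerance = 1e-9,
                     info = sprintf("b=%d n=%d", b, n))
    }
})

test_that("McNemar is symmetric in the two classifiers and restrictable", {
    tr <- c(p1 = "MSI-H", p2 = "MSI-H", p3 = "MSI-H", n1 = "MSS",
            n2 = "MSS", n3 = "MSS", n4 = "MSS")
    ca <- c(p1 = "MSI-H", p2 = "MSS", p3 = "MSI-H", n1 = "MSS",
            n2 = "MSI-H", n3 = "MSS", n4 = "MSS")
    cb <- c(p1 = "MSS", p2 = "MSI-H", p3 = "MSI-H", n1 = "MSS",
            n2 = "MSS", n3 = "MSI-H", n4 = "MSS")
    ab <- mcnemarPaired(ca, cb, tr)
    ba <- mcnemarPaired(cb, ca, tr)
    expect_equal(c(ab$b, ab$c), c(ba$c, ba$b))
    expect_equal(ab$p.value, ba$p.value)
    pos <- mcnemarPaired(ca, cb, tr, restrict = "positive")
    expect_equal(pos$n, 2L)   # p1, p2 discordant among truth-positives
    neg <- mcnemarPaired(ca, cb, tr, restrict = "negative")
    expect_equal(neg$n, 2L)   # n2, n3 discordant among truth-negatives
    expect_error(mcnemarPaired(ca[1:5], cb, tr), "identical samples")
})
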