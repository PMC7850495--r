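# Independent brute-force oracles used to cross-check the implementation.

# Skewness oracle: mean, median and n-1 sd computed from first principles
# (explicit sums and order statistics), no calls into the package.
psc_oracle <- function(x) {
    n <- length(x)
    stopifnot(n >= 1L)
    m <- sum(x) / n
    s <- sort(x)
    med <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else
        (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
    if (n == 1L) return(0)
    v <- sum((x - m)^2) / (n - 1L)
    if (v == 0) return(0)
    3 * (m - med) / sqrt(v)
}

# Tract-length oracle: materializes the full per-base reference map of an
# alignment (one entry per reference base: "M", "D" or "N"; insertions kept
# as events at their reference breakpoint), then applies the spanning and
# counting rules by direct enumeration.
tract_oracle <- function(pos, cigar, start0, end0, flank = 5L) {
    toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
    if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
        return(NA_integer_)
    ops <- substring(toks, nchar(toks))
    lens <- as.integer(sub(".$", "", toks))
    ref_pos <- integer(0)     # 0-based reference positions touched
    ref_op <- character(0)
    ins_at <- integer(0)      # reference breakpoints of insertions
    ins_len <- integer(0)
    r <- pos - 1L
    for (k in seq_along(ops)) {
        op <- ops[k]
        if (op %in% c("M", "=", "X", "D", "N")) {
            for (j in seq_len(lens[k])) {      # one base at a time
                ref_pos <- c(ref_pos, r)
                ref_op <- c(ref_op,
                            if (op %in% c("M", "=", "X")) "M" else op)
                r <- r + 1L
            }
        } else if (op == "I") {
            ins_at <- c(ins_at, r)
            ins_len <- c(ins_len, lens[k])
        }
    }
    win <- seq.int(start0 - flank, end0 + flank - 1L)
    covered <- win %in% ref_pos[ref_op %in% c("M", "D")]
    skipped <- win %in% ref_pos[ref_op == "N"]
    if (!all(covered) || any(skipped)) return(NA_integer_)
    del <- sum(ref_pos >= start0 & ref_pos < end0 & ref_op == "D")
    ins <- sum(ins_len[ins_at > start0 & ins_at < end0])
    (end0 - start0) + ins - del
}

# Random single-read alignments around a marker, exercising clips, indels
# and skips in arbitrary positions.
random_alignment <- function(start0, end0) {
    pos <- start0 - sample(0:40, 1L) + 1L    # 1-based POS
    n_blocks <- sample(1:5, 1L)
    ops <- "M"
    lens <- sample(5:40, 1L)
    for (b in seq_len(n_blocks)) {
        mid <- sample(c("I", "D", "N"), 1L, prob = c(0.4, 0.4, 0.2))
        ops <- c(ops, mid, "M")
        lens <- c(lens, sample(1:6, 1L), sample(5:40, 1L))
    }
    if (stats::runif(1) < 0.3) {
        ops <- c("S", ops)
        lens <- c(sample(1:10, 1L), lens)
    }
    if (stats::runif(1) < 0.3) {
        ops <- c(ops, "S")
        lens <- c(lens, sample(1:10, 1L))
    }
    list(pos = pos, cigar = paste0(lens, ops, collapse = ""))
}

# Convenience: LengthDistributions from a plain list of delta vectors.
make_ld <- function(..., sample_id = "s", ref_length = 100L) {
    LengthDistributions(list(...), sample_id = sample_id,
                        ref_length = ref_length)
}

panel23_path <- function() system.file("extdata", "panel23.tsv",
                                       package = "msiskew")

`%||%` <- function(a, b) if (is.null(a)) b else a
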