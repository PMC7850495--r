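# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All seeded entry points funnel through here so
# no function perturbs global RNG state.
withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        stats::runif(1)  # force RNG initialisation
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    force(code)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                lower_open = FALSE, upper_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
        (if (lower_open) x > lower else x >= lower) &&
        (if (upper_open) x < upper else x <= upper)
    if (!ok)
        stop(sprintf("'%s' must be a single number in %s%s, %s%s", name,
            if (lower_open) "(" else "[", format(lower), format(upper),
            if (upper_open) ")" else "]"), call. = FALSE)
    invisible(x)
}
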