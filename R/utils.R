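## internal helpers

## evaluate expr under set.seed(seed), restoring the caller's RNG state
.with_seed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

.is_prob <- function(p) is.numeric(p) && !anyNA(p) && all(p >= 0 & p <= 1)

## round-half-away-from-zero to `digits` decimals (printed-style percentages;
## base round() is round-half-even)
.round_half_away <- function(x, digits = 1L) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}
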