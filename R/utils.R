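# Internal helpers.

# Run code with a local RNG state: seeds deterministically, then restores
# whatever global state existed. Keeps all package randomness explicit.
with_rng <- function(seed, code) {
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
    force(code)
}

# Maximal runs of TRUE in a logical vector (NA treated as FALSE).
# Returns a data.frame with columns first, last, length.
true_runs <- function(flag) {
    flag[is.na(flag)] <- FALSE
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(first = starts[keep], last = ends[keep],
               length = r$lengths[keep])
}

# Mean of defined matrix entries; NA (flagged) when none are defined.
mean_defined <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
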