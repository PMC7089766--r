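# internal helpers shared across modules

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
    if (x < lower || x > upper)
        stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                     format(lower), format(upper), format(x)), call. = FALSE)
    invisible(x)
}

.assertCount <- function(x, name, min = 0L) {
    .assertScalarNumber(x, name, lower = min)
    if (x != as.integer(x))
        stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
    invisible(as.integer(x))
}

# deterministic 31-adic string hash, kept below 2^31 so it can seed R's RNG
.stringHash <- function(x) {
    h <- 0
    for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
}

#' Derive a per-sample RNG seed
#'
#' Combines the run-level seed with a hash of the sample identifier so that
#' each simulated sample draws from an independent, reproducible stream.
#'
#' @param seed Integer run-level seed.
#' @param sampleId Character sample identifier.
#' @return A single integer seed below 2^31.
#' @export
deriveSampleSeed <- function(seed, sampleId) {
    .assertCount(seed, "seed")
    stopifnot(is.character(sampleId), length(sampleId) == 1L)
    as.integer((as.numeric(seed) * 2654435 + .stringHash(sampleId)) %% 2147483647)
}

.chromSizesOk <- function(chromSizes) {
    is.numeric(chromSizes) && length(chromSizes) >= 1L &&
        !is.null(names(chromSizes)) && all(nzchar(names(chromSizes))) &&
        !anyDuplicated(names(chromSizes)) && all(chromSizes >= 1)
}
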