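# independent oracles, deliberately naive

# verbatim window-rule enumerator for the maximum resection endpoint:
# scan every window of wb consecutive bins; at the first with more than half
# of its bins at or below background, the last above-background bin inside it
# (else the last one before it, else none) marks the endpoint; cap at the
# scan end if no window qualifies
bruteEndpoint <- function(bins, bg, wb = 10, binBp = 50) {
    n <- length(bins)
    for (k in 1:(n - wb + 1)) {
        nBelow <- 0
        for (j in k:(k + wb - 1)) if (bins[j] <= bg) nBelow <- nBelow + 1
        if (nBelow > wb / 2) {
            last <- 0
            for (j in k:(k + wb - 1)) if (bins[j] > bg) last <- j
            if (last == 0)
                for (j in seq_len(k - 1)) if (bins[j] > bg) last <- j
            return(binBp * last)
        }
    }
    binBp * n
}

# Pearson r from first principles
pearsonByHand <- function(a, b) {
    ma <- sum(a) / length(a)
    mb <- sum(b) / length(b)
    sum((a - ma) * (b - mb)) /
        sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
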