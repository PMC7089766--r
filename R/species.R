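## clamp into [0, 1]; count clamp events for QC
.clamp01 <- function(x) {
    n <- sum(x < 0 | x > 1, na.rm = TRUE)
    list(value = pmin(pmax(x, 0), 1), nClamped = n)
}

#' Protein-free DSB fraction from the exonuclease differential
#'
#' ExoT blunts only protein-free break ends while ExoVII+ExoT blunts both
#' protein-linked and protein-free ends, so the ratio of ExoT signal to
#' ExoVII+ExoT signal at a site is the fraction of its lesions already
#' processed to protein-free DSBs. Ratios outside [0, 1] (sampling noise)
#' are clamped with a warning; sites with non-positive ExoVII+ExoT signal
#' are returned as \code{NA} with a warning.
#'
#' @param signalExoT ExoT-only signal (vectorized).
#' @param signalExoVIIExoT ExoVII+ExoT signal on the same scale.
#' @return Fraction(s) in [0, 1] (or \code{NA} for excluded sites).
#' @export
dsbFraction <- function(signalExoT, signalExoVIIExoT) {
    bad <- signalExoVIIExoT <= 0
    if (any(bad)) {
        warning(sum(bad), " site(s) excluded: non-positive ExoVII+ExoT signal")
        signalExoVIIExoT[bad] <- NA_real_
    }
    cl <- .clamp01(signalExoT / signalExoVIIExoT)
    if (cl$nClamped > 0)
        warning(cl$nClamped, " DSB fraction(s) clamped into [0, 1]")
    cl$value
}

#' Reversible TOP2cc fraction from washout loss
#'
#' The signal lost between the pre-washout and post-washout ExoVII+ExoT
#' samples is attributed to TOP2 cleavage complexes that re-ligated their
#' break on drug removal: \code{(pre - washout) / pre}, clamped to [0, 1].
#'
#' @param signalPreWashout Pre-washout signal (> 0, vectorized).
#' @param signalWashout Post-washout signal on the same scale.
#' @return Fraction(s) in [0, 1] (or \code{NA} for excluded sites).
#' @export
reversibleFraction <- function(signalPreWashout, signalWashout) {
    bad <- signalPreWashout <= 0
    if (any(bad)) {
        warning(sum(bad), " site(s) excluded: non-positive pre-washout signal")
        signalPreWashout[bad] <- NA_real_
    }
    cl <- .clamp01((signalPreWashout - signalWashout) / signalPreWashout)
    if (cl$nClamped > 0)
        warning(cl$nClamped, " reversible fraction(s) clamped into [0, 1]")
    cl$value
}

## core decomposition; inputs already on a common scale, pre > 0
.classifyOne <- function(pre, washout, exoT) {
    nCl <- 0L
    rev <- (pre - washout) / pre
    dsb <- exoT / pre
    for (v in list(rev, dsb)) nCl <- nCl + sum(v < 0 | v > 1)
    rev <- min(max(rev, 0), 1)
    dsb <- min(max(dsb, 0), 1)
    irr <- 1 - dsb - rev
    if (irr < 0) { nCl <- nCl + 1L; irr <- 0 }
    s <- dsb + rev + irr
    c(dsb = dsb / s, reversible = rev / s, irreversible = irr / s,
      nClamped = nCl)
}

#' Decompose per-site signal into lesion species
#'
#' All fractions are expressed relative to the pre-washout ExoVII+ExoT
#' signal (the initial lesion pool): the reversible TOP2cc fraction is the
#' washout loss \code{(pre - washout0h) / pre}, the protein-free DSB
#' fraction is \code{exoT0h / pre}, and the irreversible TOP2cc fraction is
#' the remainder \code{1 - dsb - reversible}, clamped at 0 and the triple
#' renormalized to sum exactly to 1. Signals must share a scale;
#' spike-normalized cell-percentages make libraries comparable.
#'
#' @param signalPre Pre-washout ExoVII+ExoT signal (> 0, vectorized).
#' @param signalWashout0h 0 hr washout ExoVII+ExoT signal.
#' @param signalExoT0h 0 hr washout ExoT-only signal.
#' @param siteId Optional site identifiers for the output.
#' @return data.frame: \code{site_id, dsb, reversible, irreversible,
#'   n_clamped}; rows with non-positive \code{signalPre} are dropped with a
#'   warning.
#' @export
classifySpecies <- function(signalPre, signalWashout0h, signalExoT0h,
                            siteId = NULL) {
    n <- length(signalPre)
    stopifnot(length(signalWashout0h) == n, length(signalExoT0h) == n)
    if (is.null(siteId)) siteId <- sprintf("site_%d", seq_len(n))
    ok <- !is.na(signalPre) & signalPre > 0
    if (!all(ok))
        warning(sum(!ok), " site(s) excluded: non-positive pre-washout signal")
    res <- t(vapply(which(ok), function(i)
        .classifyOne(signalPre[i], signalWashout0h[i], signalExoT0h[i]),
        numeric(4)))
    data.frame(site_id = siteId[ok], dsb = res[, "dsb"],
               reversible = res[, "reversible"],
               irreversible = res[, "irreversible"],
               n_clamped = as.integer(res[, "nClamped"]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-wide species decomposition
#'
#' \code{"POOLED"} sums the per-site signals across the genome before taking
#' ratios (a read-weighted aggregate); \code{"PER_SITE_MEAN"} averages the
#' per-site fraction triples. Both return a valid
#' \linkS4class{SpeciesFractions} summing to 1.
#'
#' @param signalPre,signalWashout0h,signalExoT0h Per-site signals on a
#'   common scale (see \code{\link{classifySpecies}}).
#' @param aggregation \code{"POOLED"} (default) or \code{"PER_SITE_MEAN"}.
#' @return A \linkS4class{SpeciesFractions}.
#' @export
classifyGenomewide <- function(signalPre, signalWashout0h, signalExoT0h,
                               aggregation = c("POOLED", "PER_SITE_MEAN")) {
    aggregation <- match.arg(aggregation)
    ok <- !is.na(signalPre) & signalPre > 0
    if (!any(ok)) stop("no valid sites (pre-washout signal <= 0 everywhere)",
                       call. = FALSE)
    if (aggregation == "POOLED") {
        v <- .classifyOne(sum(signalPre[ok]), sum(signalWashout0h[ok]),
                          sum(signalExoT0h[ok]))
        speciesFractions(v[["dsb"]], v[["reversible"]], v[["irreversible"]],
                         nClamped = v[["nClamped"]])
    } else {
        per <- t(vapply(which(ok), function(i)
            .classifyOne(signalPre[i], signalWashout0h[i], signalExoT0h[i]),
            numeric(4)))
        m <- colMeans(per[, c("dsb", "reversible", "irreversible"),
                          drop = FALSE])
        m <- m / sum(m)
        speciesFractions(m[["dsb"]], m[["reversible"]], m[["irreversible"]],
                         nClamped = sum(per[, "nClamped"]))
    }
}
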