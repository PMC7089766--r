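#' Per-break persistence ratio
#'
#' Persistence of a TOP2-mediated DSB is the ratio of its peak signal at a
#' washout timepoint to its initial (pre-washout) signal. Any common scale
#' (RPKM or spike-normalized cell-percentage) cancels; ratios above 1 are
#' reported, not clipped. Initial signal must be positive.
#'
#' @param signalTimepoint Signal at the washout timepoint (vectorized).
#' @param signalInitial Matching initial signal (> 0).
#' @return Persistence ratio(s), >= 0.
#' @export
persistenceRatio <- function(signalTimepoint, signalInitial) {
    if (any(signalInitial <= 0))
        stop("persistence undefined: initial signal must be > 0", call. = FALSE)
    signalTimepoint / signalInitial
}

#' Fraction of initial breaks still detected at a timepoint
#'
#' @param detectedInitial Site identifiers detected in the initial sample
#'   (non-empty).
#' @param detectedTimepoint Site identifiers detected at the timepoint.
#' @return Percent in [0, 100].
#' @export
fractionInitialBreaks <- function(detectedInitial, detectedTimepoint) {
    detectedInitial <- unique(detectedInitial)
    if (length(detectedInitial) == 0L)
        stop("no initially detected breaks", call. = FALSE)
    100 * length(intersect(unique(detectedTimepoint), detectedInitial)) /
        length(detectedInitial)
}

#' Per-site persistence across timepoints with a genome-wide summary
#'
#' Takes a matrix-like of per-site signal (rows = sites, columns = samples or
#' timepoints; one column is the initial, pre-washout reference) and returns
#' one persistence record per site and timepoint plus per-timepoint summary
#' quantiles. Sites with zero or missing signal at a timepoint contribute a
#' ratio of 0 (dropping them would bias persistence upward); sites with
#' non-positive initial signal are excluded with a warning.
#'
#' @param signals data.frame or matrix of per-site signal with row names (or
#'   a \code{site_id} column) identifying sites.
#' @param initial Name of the initial (pre-washout) column.
#' @param detected Optional logical matrix (same shape) of per-timepoint
#'   detection flags.
#' @return List with \code{records} (site_id, timepoint, persistence,
#'   detected_at_timepoint) and \code{summary} (timepoint, n, mean, median,
#'   q25, q75).
#' @export
persistenceTable <- function(signals, initial, detected = NULL) {
    signals <- as.data.frame(signals)
    if ("site_id" %in% names(signals)) {
        rownames(signals) <- signals$site_id
        signals$site_id <- NULL
    }
    if (!initial %in% names(signals))
        stop("initial column '", initial, "' not found", call. = FALSE)
    tps <- setdiff(names(signals), initial)
    init <- signals[[initial]]
    ok <- !is.na(init) & init > 0
    if (!all(ok))
        warning(sum(!ok), " site(s) excluded: non-positive initial signal")
    records <- do.call(rbind, lapply(tps, function(tp) {
        v <- signals[[tp]][ok]
        v[is.na(v)] <- 0
        data.frame(site_id = rownames(signals)[ok], timepoint = tp,
                   persistence = v / init[ok],
                   detected_at_timepoint = if (is.null(detected)) NA
                       else detected[ok, tp],
                   stringsAsFactors = FALSE)
    }))
    summary <- do.call(rbind, lapply(tps, function(tp) {
        p <- records$persistence[records$timepoint == tp]
        p <- p[is.finite(p)]
        data.frame(timepoint = tp, n = length(p), mean = mean(p),
                   median = median(p),
                   q25 = unname(quantile(p, 0.25)),
                   q75 = unname(quantile(p, 0.75)),
                   stringsAsFactors = FALSE)
    }))
    list(records = records, summary = summary)
}
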