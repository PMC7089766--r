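#' Fold-enrichment detection of break sites over a control
#'
#' A candidate site is detected when its treated RPKM exceeds
#' \code{foldThreshold} times its control RPKM, with a pseudocount added to
#' the control so sites with empty control windows are scored (the analog of
#' peak calling against an untreated library with a >10-fold filter).
#'
#' @param track Treated-sample \linkS4class{CoverageTrack}.
#' @param control Control \linkS4class{CoverageTrack} (same bin width).
#' @param sites Candidate break sites (\code{GRanges} with \code{site_id}).
#' @param foldThreshold Enrichment ratio that must be exceeded (default 10).
#' @param pseudocountRpkm Added to the control RPKM only (default 0.1).
#' @return data.frame: \code{site_id, rpkm, rpkm_control, fold, detected}.
#' @export
detectSites <- function(track, control, sites, foldThreshold = 10,
                        pseudocountRpkm = 0.1) {
    stopifnot(is(track, "CoverageTrack"), is(control, "CoverageTrack"))
    if (binWidth(track) != binWidth(control))
        stop("treated and control tracks must share a bin width", call. = FALSE)
    r <- rpkm(track, sites)
    rc <- rpkm(control, sites)
    fold <- r / (rc + pseudocountRpkm)
    data.frame(site_id = mcols(sites)$site_id, rpkm = r, rpkm_control = rc,
               fold = fold, detected = fold > foldThreshold,
               stringsAsFactors = FALSE)
}

#' Spike-in normalization statistics from a coverage track
#'
#' Computes RPKM in a window centered on each zinc-finger-nuclease spike-in
#' summit and summarizes by the arithmetic mean. Because the spike-in cells
#' carry their break at a known, fixed fraction of the library, this mean
#' anchors the conversion of peak RPKM to cell-percentage.
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param spikeSites Spike-in summits: either a data.frame with \code{chrom}
#'   and \code{summit} (0-based) or a \code{GRanges} with a \code{summit}
#'   metadata column.
#' @param windowBp Total window width centered on the summit (default 5000,
#'   matching the default break-site window of \code{\link{breakSites}}; the
#'   cell-percentage conversion is only calibrated when peak and spike
#'   windows share a width, since RPKM's per-kilobase factor then cancels).
#' @param spikeInFraction Spike-in cell fraction of the library
#'   (default 0.025, the 1:40 ratio).
#' @return A \linkS4class{SpikeInStats}.
#' @export
spikeInFactor <- function(track, spikeSites, windowBp = 5000L,
                          spikeInFraction = 0.025) {
    if (is.data.frame(spikeSites)) {
        if (nrow(spikeSites) == 0L)
            stop("at least one spike-in site required", call. = FALSE)
        win <- breakSites(spikeSites$chrom, spikeSites$summit,
                          flank = as.integer(windowBp / 2),
                          siteId = spikeSites$site_id,
                          chromSizes = chromSizes(track))
    } else {
        if (length(spikeSites) == 0L)
            stop("at least one spike-in site required", call. = FALSE)
        win <- breakSites(as.character(seqnames(spikeSites)),
                          mcols(spikeSites)$summit,
                          flank = as.integer(windowBp / 2),
                          siteId = mcols(spikeSites)$site_id,
                          chromSizes = chromSizes(track))
    }
    per <- rpkm(track, win)
    m <- mean(per)
    if (m == 0)
        stop("zero spike-in signal at every spike-in site: cannot normalize",
             call. = FALSE)
    new("SpikeInStats", perSiteRpkm = per, meanRpkm = m,
        spikeInFraction = spikeInFraction)
}

#' Cell-percentage conversion factor
#'
#' The scalar that multiplies a spike-normalized per-peak RPKM
#' (\code{rpkm_peak / mean_spike_rpkm}) to express signal as the percentage
#' of cells bearing the lesion: \code{100 * spikeInFraction}. With spike-in
#' cells mixed at 1:40 (fraction 0.025) the factor is 2.5.
#'
#' @param spikeInFraction Spike-in cell fraction in (0, 1).
#' @return The multiplicative factor.
#' @export
cellPercentageFactor <- function(spikeInFraction) {
    .assertScalarNumber(spikeInFraction, "spikeInFraction", 0, 1)
    if (spikeInFraction == 0)
        stop("spike-in fraction of 0 cannot anchor a cell-percentage scale",
             call. = FALSE)
    100 * spikeInFraction
}

#' Convert peak RPKM to cell-percentage
#'
#' Each peak's RPKM is divided by the mean spike-in RPKM and multiplied by
#' \code{\link{cellPercentageFactor}} (2.5 at the 1:40 spike ratio), yielding
#' the percent of cells bearing the lesion.
#'
#' @param rpkmPeak Peak RPKM value(s).
#' @param spike A \linkS4class{SpikeInStats}.
#' @return Cell-percentage value(s).
#' @export
toCellPercentage <- function(rpkmPeak, spike) {
    stopifnot(is(spike, "SpikeInStats"))
    if (meanRpkm(spike) <= 0)
        stop("spike-in mean RPKM must be > 0", call. = FALSE)
    rpkmPeak / meanRpkm(spike) * cellPercentageFactor(spikeInFraction(spike))
}

#' Quantify break sites in one sample
#'
#' Per-site RPKM within the site window, optional fold-enrichment detection
#' against a control track, and optional spike-in conversion to
#' cell-percentage.
#'
#' @param track Sample \linkS4class{CoverageTrack}.
#' @param sites Break sites (\code{GRanges} with \code{site_id} and
#'   \code{summit}).
#' @param control Optional control \linkS4class{CoverageTrack}.
#' @param spike Optional \linkS4class{SpikeInStats}.
#' @param foldThreshold,pseudocountRpkm Passed to \code{\link{detectSites}}.
#' @return data.frame: \code{site_id, chrom, summit, rpkm, cell_percentage,
#'   detected} (\code{cell_percentage}/\code{detected} are \code{NA} when
#'   \code{spike}/\code{control} are absent).
#' @export
quantifyBreaks <- function(track, sites, control = NULL, spike = NULL,
                           foldThreshold = 10, pseudocountRpkm = 0.1) {
    r <- rpkm(track, sites)
    out <- data.frame(site_id = mcols(sites)$site_id,
                      chrom = as.character(seqnames(sites)),
                      summit = mcols(sites)$summit,
                      rpkm = r,
                      cell_percentage = NA_real_,
                      detected = NA,
                      stringsAsFactors = FALSE)
    if (!is.null(spike)) out$cell_percentage <- toCellPercentage(r, spike)
    if (!is.null(control))
        out$detected <- detectSites(track, control, sites, foldThreshold,
                                    pseudocountRpkm)$detected
    out
}

#' Overlap two break-site lists by summit proximity
#'
#' Summits within \code{maxSummitDistance} on the same chromosome are
#' matched greedily nearest-first, each site used at most once (the Venn
#' counts of shared and condition-specific break sites).
#'
#' @param a,b Break-site \code{GRanges} with \code{summit} metadata.
#' @param maxSummitDistance Maximum summit distance in bp (default 250).
#' @return Named integer vector \code{c(a_only, shared, b_only)}.
#' @export
overlapSites <- function(a, b, maxSummitDistance = 250L) {
    if (length(a) == 0L || length(b) == 0L)
        return(c(a_only = length(a), shared = 0L, b_only = length(b)))
    pa <- GRanges(seqnames(a), IRanges(mcols(a)$summit + 1, width = 1L))
    pb <- GRanges(seqnames(b), IRanges(mcols(b)$summit + 1, width = 1L))
    # disjoint chromosome sets are a legitimate comparison, not a warning
    hits <- suppressWarnings(findOverlaps(pa, pb,
                                          maxgap = maxSummitDistance,
                                          ignore.strand = TRUE))
    if (length(hits) == 0L)
        return(c(a_only = length(a), shared = 0L, b_only = length(b)))
    qa <- queryHits(hits); qb <- subjectHits(hits)
    d <- abs(mcols(a)$summit[qa] - mcols(b)$summit[qb])
    keep <- d <= maxSummitDistance
    qa <- qa[keep]; qb <- qb[keep]; d <- d[keep]
    if (length(d) == 0L)
        return(c(a_only = length(a), shared = 0L, b_only = length(b)))
    o <- order(d, qa, qb)
    usedA <- logical(length(a)); usedB <- logical(length(b))
    shared <- 0L
    for (k in o) {
        if (!usedA[qa[k]] && !usedB[qb[k]]) {
            usedA[qa[k]] <- TRUE; usedB[qb[k]] <- TRUE
            shared <- shared + 1L
        }
    }
    c(a_only = length(a) - shared, shared = shared, b_only = length(b) - shared)
}

#' Pearson correlation between replicate per-site signals
#'
#' @param signalA,signalB Equal-length (>= 3) numeric vectors of per-site
#'   signal, paired by site.
#' @return Pearson r in [-1, 1].
#' @export
correlateReplicates <- function(signalA, signalB) {
    if (length(signalA) != length(signalB) || length(signalA) < 3L)
        stop("need equal-length paired vectors of length >= 3", call. = FALSE)
    if (stats::sd(signalA) == 0 || stats::sd(signalB) == 0)
        stop("correlation undefined: zero variance", call. = FALSE)
    stats::cor(signalA, signalB, method = "pearson")
}

#' Fold change between two counts
#'
#' Convenience ratio used for arm-level comparisons such as resected-break
#' counts between treatment arms.
#'
#' @param numerator,denominator Positive counts.
#' @return \code{numerator / denominator}.
#' @export
foldChange <- function(numerator, denominator) {
    .assertScalarNumber(numerator, "numerator", 0)
    .assertScalarNumber(denominator, "denominator")
    if (denominator <= 0) stop("denominator must be > 0", call. = FALSE)
    numerator / denominator
}
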