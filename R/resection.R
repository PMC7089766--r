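#' @include AllClasses.R io.R
NULL

## resection scan geometry: 50 bp bins, 50 signal bins (summit to 2.5 kb),
## 50 background bins (2.5 to 5 kb), per side
.RES_BIN <- 50L
.RES_NSIG <- 50L
.RES_NTOT <- 100L

.newBinProfile <- function(siteId, side, counts, totalReads) {
    rpkmPerBin <- counts / ((.RES_BIN / 1000) * (totalReads / 1e6))
    new("BinProfile", siteId = as.character(siteId), side = side,
        binWidth = .RES_BIN,
        signalBins = rpkmPerBin[seq_len(.RES_NSIG)],
        backgroundBins = rpkmPerBin[(.RES_NSIG + 1L):.RES_NTOT])
}

.checkSiteFlanks <- function(s0, chrom, sizes) {
    span <- .RES_BIN * .RES_NTOT
    if (length(sizes) == 0L) return(TRUE)
    s0 >= span && s0 + span <= sizes[[chrom]]
}

#' @describeIn binProfile Exact summit-anchored profile from raw read ends.
#'   Bin i on the right covers 0-based \code{[summit + (i-1)*50, summit +
#'   i*50)}; left bins mirror it. In \code{"stranded"} mode the left profile
#'   counts minus-strand reads and the right profile plus-strand reads.
#' @param mode \code{"unstranded"} (default) or \code{"stranded"}.
#' @export
setMethod("binProfile", "ReadEndSet", function(x, site,
                                               mode = c("unstranded",
                                                        "stranded"), ...) {
    mode <- match.arg(mode)
    stopifnot(length(site) == 1L)
    s0 <- mcols(site)$summit
    chrom <- as.character(seqnames(site))
    if (!.checkSiteFlanks(s0, chrom, chromSizes(x)))
        stop("summit within 5 kb of a chromosome end: ",
             mcols(site)$site_id, call. = FALSE)
    gr <- readEnds(x)
    sel <- as.character(seqnames(gr)) == chrom
    p0 <- start(gr)[sel] - 1L
    str <- as.character(strand(gr))[sel]
    total <- totalReads(x)
    span <- .RES_BIN * .RES_NTOT
    useR <- p0 >= s0 & p0 < s0 + span
    useL <- p0 < s0 & p0 >= s0 - span
    if (mode == "stranded") {
        useR <- useR & str == "+"
        useL <- useL & str == "-"
    }
    cntR <- tabulate((p0[useR] - s0) %/% .RES_BIN + 1L, nbins = .RES_NTOT)
    cntL <- tabulate((s0 - p0[useL] - 1L) %/% .RES_BIN + 1L, nbins = .RES_NTOT)
    list(left = .newBinProfile(mcols(site)$site_id, "LEFT", cntL, total),
         right = .newBinProfile(mcols(site)$site_id, "RIGHT", cntR, total))
})

#' @describeIn binProfile Profile from a 50 bp binned track; the summit is
#'   snapped to the nearest bin boundary (at most half a bin of shift).
#'   Stranded mode requires a track built with \code{stranded = TRUE}.
#' @export
setMethod("binProfile", "CoverageTrack", function(x, site,
                                                  mode = c("unstranded",
                                                           "stranded"), ...) {
    mode <- match.arg(mode)
    stopifnot(length(site) == 1L)
    if (binWidth(x) != .RES_BIN)
        stop("resection profiles need a ", .RES_BIN, " bp binned track",
             call. = FALSE)
    if (mode == "stranded" && !isStranded(x))
        stop("stranded mode requires a stranded coverage track", call. = FALSE)
    s0 <- mcols(site)$summit
    chrom <- as.character(seqnames(site))
    if (!.checkSiteFlanks(s0, chrom, chromSizes(x)))
        stop("summit within 5 kb of a chromosome end: ",
             mcols(site)$site_id, call. = FALSE)
    b0 <- as.integer(round(s0 / .RES_BIN))  # summit snapped to bin boundary
    grab <- function(v, idx) ifelse(idx >= 1L & idx <= length(v), v[idx], 0)
    srcR <- if (mode == "stranded") x@countsPlus[[chrom]] else x@counts[[chrom]]
    srcL <- if (mode == "stranded") x@countsMinus[[chrom]] else x@counts[[chrom]]
    cntR <- grab(srcR, b0 + seq_len(.RES_NTOT))
    cntL <- grab(srcL, b0 + 1L - seq_len(.RES_NTOT))
    list(left = .newBinProfile(mcols(site)$site_id, "LEFT", cntL,
                               totalReads(x)),
         right = .newBinProfile(mcols(site)$site_id, "RIGHT", cntR,
                                totalReads(x)))
})

#' Background level of a bin profile
#'
#' The maximum RPKM over the 50 background bins (2.5-5 kb from the summit).
#'
#' @param profile A \linkS4class{BinProfile}.
#' @return Background RPKM.
#' @export
backgroundLevel <- function(profile) {
    stopifnot(is(profile, "BinProfile"))
    max(profile@backgroundBins)
}

#' Maximum resection endpoint by sliding-window scan
#'
#' Slides a window of \code{windowBins} consecutive 50 bp bins (stride one
#' bin) outward from the summit over the 50 signal bins. At the first window
#' position where more than half of the bins have signal at or below the
#' background, the last bin within that window with signal above background
#' marks the maximum resection endpoint (\code{50 * bin index} bp). If that
#' window contains no above-background bin, the last above-background bin
#' before the window is used (0 if none). If no window ever triggers, the
#' endpoint is capped at 2500 bp, the end of the scan range.
#'
#' @param profile A \linkS4class{BinProfile} or a numeric vector of 50
#'   signal-bin RPKM values.
#' @param background Background RPKM; defaults to
#'   \code{\link{backgroundLevel}} of the profile.
#' @param windowBins Window length in bins (default 10).
#' @return Endpoint distance from the summit in bp, in [0, 2500].
#' @export
maxResectionEndpoint <- function(profile, background = NULL,
                                 windowBins = 10L) {
    bins <- if (is(profile, "BinProfile")) profile@signalBins else profile
    bw <- if (is(profile, "BinProfile")) profile@binWidth else .RES_BIN
    if (is.null(background)) {
        if (!is(profile, "BinProfile"))
            stop("background required for a bare bin vector", call. = FALSE)
        background <- backgroundLevel(profile)
    }
    n <- length(bins)
    stopifnot(n >= windowBins, windowBins >= 1L)
    below <- bins <= background
    for (k in seq_len(n - windowBins + 1L)) {
        win <- k:(k + windowBins - 1L)
        if (sum(below[win]) > windowBins / 2) {
            above <- win[!below[win]]
            if (length(above)) return(bw * max(above))
            prior <- which(!below[seq_len(k - 1L)])
            return(if (length(prior)) bw * max(prior) else 0)
        }
    }
    bw * n
}

.callResectionCore <- function(x, sites, mode, minResection, backgrounds,
                               windowBins) {
    keep <- vapply(seq_along(sites), function(i)
        .checkSiteFlanks(mcols(sites)$summit[i],
                         as.character(seqnames(sites))[i], chromSizes(x)),
        logical(1))
    if (!all(keep))
        warning(sum(!keep), " site(s) skipped: summit within 5 kb of a ",
                "chromosome end")
    rows <- lapply(which(keep), function(i) {
        prof <- binProfile(x, sites[i], mode = mode)
        bgL <- backgroundLevel(prof$left)
        bgR <- backgroundLevel(prof$right)
        if (backgrounds == "pooled") bgL <- bgR <- max(bgL, bgR)
        epL <- maxResectionEndpoint(prof$left, bgL, windowBins)
        epR <- maxResectionEndpoint(prof$right, bgR, windowBins)
        data.frame(site_id = mcols(sites)$site_id[i],
                   endpoint_left = epL, endpoint_right = epR,
                   max_endpoint = max(epL, epR),
                   background_left = bgL, background_right = bgR,
                   resected = max(epL, epR) > minResection,
                   stringsAsFactors = FALSE)
    })
    if (length(rows) == 0L)
        return(data.frame(site_id = character(), endpoint_left = numeric(),
                          endpoint_right = numeric(), max_endpoint = numeric(),
                          background_left = numeric(),
                          background_right = numeric(), resected = logical(),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' @describeIn callResection Resection calls from raw read ends.
#' @param mode \code{"unstranded"} (default) or \code{"stranded"}.
#' @param minResection Endpoint (bp) that must be exceeded for a break to
#'   count as resected (default 100).
#' @param backgrounds \code{"per_side"} (default) or \code{"pooled"}
#'   background levels.
#' @param windowBins Sliding-window length in bins (default 10).
#' @export
setMethod("callResection", "ReadEndSet",
          function(x, sites, mode = c("unstranded", "stranded"),
                   minResection = 100, backgrounds = c("per_side", "pooled"),
                   windowBins = 10L, ...) {
    .callResectionCore(x, sites, match.arg(mode), minResection,
                       match.arg(backgrounds), windowBins)
})

#' @describeIn callResection Resection calls from a 50 bp binned track.
#' @export
setMethod("callResection", "CoverageTrack",
          function(x, sites, mode = c("unstranded", "stranded"),
                   minResection = 100, backgrounds = c("per_side", "pooled"),
                   windowBins = 10L, ...) {
    .callResectionCore(x, sites, match.arg(mode), minResection,
                       match.arg(backgrounds), windowBins)
})

#' Stratify persistence by resection status
#'
#' Partitions break sites into resected and non-resected groups and compares
#' their persistence distributions (resected breaks are expected to be the
#' more persistent ones).
#'
#' @param calls Resection calls (data.frame from \code{\link{callResection}}).
#' @param persistence Persistence records for one timepoint (data.frame with
#'   \code{site_id} and \code{persistence}).
#' @return List with \code{resected} and \code{non_resected} persistence
#'   vectors and a \code{summary} data.frame (group, n, median, mean).
#' @export
stratifyByResection <- function(calls, persistence) {
    m <- merge(calls[, c("site_id", "resected")],
               persistence[, c("site_id", "persistence")], by = "site_id")
    grp <- function(flag) m$persistence[m$resected == flag]
    res <- grp(TRUE); non <- grp(FALSE)
    summary <- data.frame(
        group = c("resected", "non_resected"),
        n = c(length(res), length(non)),
        median = c(if (length(res)) median(res) else NA_real_,
                   if (length(non)) median(non) else NA_real_),
        mean = c(if (length(res)) mean(res) else NA_real_,
                 if (length(non)) mean(non) else NA_real_),
        stringsAsFactors = FALSE)
    list(resected = res, non_resected = non, summary = summary)
}
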