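#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom utils read.table write.table
NULL

# ---------------------------------------------------------------------------
# BED / chrom sizes
# ---------------------------------------------------------------------------

#' Read a BED file
#'
#' Parses 3- to 6-column BED (0-based half-open) into a 1-based
#' \link[GenomicRanges]{GRanges}. When a 7th column is present it is taken as
#' a break-summit coordinate (0-based, as written by \code{\link{writeSites}})
#' and stored in the \code{summit} metadata column, with column 4 as
#' \code{site_id}. Malformed lines raise an error naming the line number.
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges}; zero-length for an empty file.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
    df <- tryCatch(
        read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", colClasses = "character"),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                return(data.frame())
            stop("BED parse error in ", path, ": ", conditionMessage(e),
                 call. = FALSE)
        })
    if (nrow(df) == 0L) return(GRanges())
    if (ncol(df) < 3L)
        stop("BED parse error in ", path, ": fewer than 3 columns", call. = FALSE)
    start0 <- suppressWarnings(as.numeric(df[[2L]]))
    end0 <- suppressWarnings(as.numeric(df[[3L]]))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
    if (length(bad))
        stop(sprintf("BED parse error in %s at line %d: need 0 <= start < end, got '%s'\t'%s'",
                     path, bad[1L], df[bad[1L], 2L], df[bad[1L], 3L]), call. = FALSE)
    str <- if (ncol(df) >= 6L) {
        s <- df[[6L]]
        ok <- s %in% c("+", "-", ".")
        if (!all(ok))
            stop(sprintf("BED parse error in %s at line %d: bad strand '%s'",
                         path, which(!ok)[1L], s[which(!ok)[1L]]), call. = FALSE)
        s
    } else "*"
    str[str == "."] <- "*"
    gr <- GRanges(df[[1L]], IRanges(start0 + 1, end0), strand = str)
    if (ncol(df) >= 7L) {
        summit <- suppressWarnings(as.numeric(df[[7L]]))
        bad <- which(is.na(summit) | summit < start0 | summit >= end0)
        if (length(bad))
            stop(sprintf("BED parse error in %s at line %d: summit outside interval",
                         path, bad[1L]), call. = FALSE)
        mcols(gr)$site_id <- df[[4L]]
        mcols(gr)$summit <- summit
    } else if (ncol(df) >= 4L) {
        mcols(gr)$name <- df[[4L]]
    }
    gr
}

#' Write read ends or intervals as BED
#'
#' Read ends are written as 6-column BED (chrom, start, end = start + 1, name,
#' score 0, strand), 0-based half-open, sorted by chromosome and position so
#' that identical inputs produce byte-identical files.
#'
#' @param x A \linkS4class{ReadEndSet} or \code{GRanges}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBed <- function(x, path) {
    gr <- if (is(x, "ReadEndSet")) readEnds(x) else x
    o <- order(as.character(seqnames(gr)), start(gr), as.character(strand(gr)))
    gr <- gr[o]
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    lines <- sprintf("%s\t%d\t%d\t.\t0\t%s",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr), str)
    writeLines(lines, path)
    invisible(path)
}

#' Construct break sites from summit coordinates
#'
#' A break site is the interval summit +/- \code{flank} (clipped to the
#' chromosome) with the summit retained; all per-site statistics are computed
#' on these windows. The default 2500 bp flank spans the full resection scan
#' range so peak signal includes resected read ends.
#'
#' @param chrom Chromosome names.
#' @param summit 0-based summit coordinates (BED convention).
#' @param flank Half-width of the site window in bp.
#' @param siteId Optional identifiers (default \code{site_1, ...}).
#' @param chromSizes Optional named sizes used to clip windows.
#' @return A \code{GRanges} with \code{site_id} and \code{summit} metadata.
#' @export
breakSites <- function(chrom, summit, flank = 2500L, siteId = NULL,
                       chromSizes = NULL) {
    chrom <- rep_len(chrom, length(summit))
    if (is.null(siteId)) siteId <- sprintf("site_%d", seq_along(summit))
    start0 <- pmax(summit - flank, 0)
    end0 <- summit + flank + 1
    if (!is.null(chromSizes)) end0 <- pmin(end0, chromSizes[chrom])
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    mcols(gr)$site_id <- siteId
    mcols(gr)$summit <- as.numeric(summit)
    gr
}

#' Read and write break-site BED files
#'
#' Site files are BED6 plus a 7th column holding the 0-based summit
#' coordinate; \code{site_id} is column 4.
#'
#' @param sites \code{GRanges} with \code{site_id} and \code{summit} metadata.
#' @param path File path.
#' @return \code{readSites} returns the sites \code{GRanges};
#'   \code{writeSites} the path, invisibly.
#' @export
writeSites <- function(sites, path) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%d",
                     as.character(seqnames(sites)), start(sites) - 1L,
                     end(sites), mcols(sites)$site_id,
                     as.integer(mcols(sites)$summit))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSites
#' @export
readSites <- function(path) {
    gr <- readBed(path)
    if (length(gr) && is.null(mcols(gr)$summit))
        stop("site file lacks a summit column: ", path, call. = FALSE)
    gr
}

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a tab-separated file (chrom, length).
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "size"))
    stats::setNames(as.numeric(df$size), as.character(df$chrom))
}

# ---------------------------------------------------------------------------
# coverage
# ---------------------------------------------------------------------------

#' Bin read ends into a coverage track
#'
#' A read end at 0-based position p increments bin \code{floor(p / binWidth)}
#' of its chromosome; the genome-wide sum of bin counts equals the library
#' size.
#'
#' @param reads A \linkS4class{ReadEndSet} (or width-1 \code{GRanges}).
#' @param binWidth Bin width in bp (>= 1).
#' @param chromSizes Named chromosome lengths; defaults to the sizes attached
#'   to \code{reads}.
#' @param stranded Also keep per-strand counts (needed for the stranded
#'   resection mode).
#' @return A \linkS4class{CoverageTrack}.
#' @export
coverageFromReads <- function(reads, binWidth = 50L, chromSizes = NULL,
                              stranded = FALSE) {
    binWidth <- .assertCount(binWidth, "binWidth", 1L)
    gr <- if (is(reads, "ReadEndSet")) readEnds(reads) else reads
    if (is.null(chromSizes)) {
        if (is(reads, "ReadEndSet") && length(chromSizes(reads)))
            chromSizes <- chromSizes(reads)
        else stop("chromSizes required when reads carry none", call. = FALSE)
    }
    ch <- as.character(seqnames(gr))
    pos0 <- start(gr) - 1L
    bad <- !ch %in% names(chromSizes)
    if (any(bad))
        stop("read on unknown chromosome ", ch[bad][1L], call. = FALSE)
    over <- pos0 >= chromSizes[ch] | pos0 < 0
    if (any(over))
        stop(sprintf("read beyond chromosome end at %s:%d",
                     ch[over][1L], pos0[over][1L]), call. = FALSE)
    nbins <- ceiling(chromSizes / binWidth)
    binOne <- function(keep) {
        out <- lapply(names(chromSizes), function(cn) {
            sel <- keep & ch == cn
            tabulate(pos0[sel] %/% binWidth + 1L, nbins = nbins[[cn]])
        })
        names(out) <- names(chromSizes)
        out
    }
    counts <- binOne(rep(TRUE, length(gr)))
    cp <- cm <- list()
    if (stranded) {
        sgn <- as.character(strand(gr))
        cp <- binOne(sgn == "+")
        cm <- binOne(sgn == "-")
    }
    new("CoverageTrack", binWidth = binWidth, counts = counts,
        countsPlus = cp, countsMinus = cm,
        chromSizes = chromSizes, totalReads = as.numeric(length(gr)))
}

## sum of bin counts over 0-based [s0, e0), snapped outward to bin boundaries;
## returns c(count, snapped length in bp)
.trackWindowCount <- function(track, chrom, s0, e0, counts = track@counts) {
    bw <- track@binWidth
    v <- counts[[chrom]]
    if (is.null(v)) stop("interval on unknown chromosome ", chrom, call. = FALSE)
    b1 <- max(s0 %/% bw, 0) + 1
    b2 <- min(ceiling(e0 / bw), length(v))
    cnt <- if (b2 >= b1) sum(v[b1:b2]) else 0
    c(cnt, (b2 - b1 + 1) * bw)
}

#' @describeIn rpkm RPKM over intervals of a binned track. Intervals that are
#'   not bin-aligned are snapped outward to bin boundaries and the snapped
#'   length is used for the per-kilobase normalization.
#' @export
setMethod("rpkm", "CoverageTrack", function(x, which, ...) {
    if (x@totalReads == 0)
        stop("RPKM undefined: track has zero total reads", call. = FALSE)
    if (length(which) == 0L) return(numeric())
    ch <- as.character(seqnames(which))
    s0 <- start(which) - 1L
    e0 <- end(which)
    vapply(seq_along(which), function(i) {
        wc <- .trackWindowCount(x, ch[i], s0[i], e0[i])
        wc[1L] / ((wc[2L] / 1000) * (x@totalReads / 1e6))
    }, numeric(1))
})

# ---------------------------------------------------------------------------
# bedGraph
# ---------------------------------------------------------------------------

#' Write a coverage track as bedGraph
#'
#' Adjacent bins with equal formatted values are merged; zero bins are
#' omitted. Values are written with 6 significant digits. \code{"RPM"} scales
#' counts to reads per million; \code{"RPM_SPIKE"} additionally divides by a
#' spike-in factor so tracks from libraries of different cellular break load
#' are comparable.
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param path Output path.
#' @param scale One of \code{"RAW"}, \code{"RPM"}, \code{"RPM_SPIKE"}.
#' @param spikeFactor Divisor applied after RPM scaling (e.g.
#'   \code{meanRpkm} of a \linkS4class{SpikeInStats}); required for
#'   \code{"RPM_SPIKE"}.
#' @return Invisibly, the path.
#' @export
writeBedGraph <- function(track, path, scale = c("RAW", "RPM", "RPM_SPIKE"),
                          spikeFactor = NULL) {
    scale <- match.arg(scale)
    if (scale != "RAW" && track@totalReads == 0)
        stop("RPM scaling undefined: zero total reads", call. = FALSE)
    if (scale == "RPM_SPIKE") {
        if (is.null(spikeFactor) || spikeFactor <= 0)
            stop("spikeFactor required (and > 0) for RPM_SPIKE", call. = FALSE)
    }
    bw <- track@binWidth
    con <- file(path, "w")
    on.exit(close(con))
    for (cn in names(track@counts)) {
        v <- track@counts[[cn]]
        if (scale != "RAW") v <- v / track@totalReads * 1e6
        if (scale == "RPM_SPIKE") v <- v / spikeFactor
        v <- signif(v, 6)
        r <- rle(v)
        endBin <- cumsum(r$lengths)
        startBin <- endBin - r$lengths
        keep <- r$values != 0
        if (!any(keep)) next
        ends <- pmin(endBin[keep] * bw, track@chromSizes[[cn]])
        writeLines(sprintf("%s\t%d\t%d\t%.6g", cn,
                           as.integer(startBin[keep] * bw),
                           as.integer(ends), r$values[keep]), con)
    }
    invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @return A \code{GRanges} with a \code{score} metadata column.
#' @export
readBedGraph <- function(path) {
    rtracklayer::import(path, format = "bedGraph")
}

# ---------------------------------------------------------------------------
# blacklist
# ---------------------------------------------------------------------------

#' Remove break sites overlapping blacklisted regions
#'
#' A site is removed iff its interval overlaps any blacklist interval by at
#' least 1 bp.
#'
#' @param sites Break sites (\code{GRanges}).
#' @param blacklist Blacklist intervals (\code{GRanges}); an empty blacklist
#'   is a no-op.
#' @return The filtered sites.
#' @export
subtractBlacklist <- function(sites, blacklist) {
    if (length(blacklist) == 0L || length(sites) == 0L) return(sites)
    sites[countOverlaps(sites, blacklist, ignore.strand = TRUE) == 0L]
}
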