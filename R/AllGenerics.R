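#' @importFrom methods new validObject slot is setClass setGeneric setMethod
#'   setValidity show
NULL

#' Total number of read ends in an object
#'
#' @param x A \linkS4class{ReadEndSet} or \linkS4class{CoverageTrack}.
#' @return A single number.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Bin width of a binned object
#'
#' @param x A \linkS4class{CoverageTrack} or \linkS4class{BinProfile}.
#' @return Bin width in bp.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Chromosome sizes attached to an object
#'
#' @param x A \linkS4class{ReadEndSet} or \linkS4class{CoverageTrack}.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' END-seq signal as RPKM over intervals
#'
#' Reads per kilobase per million mapped reads, counting read ends whose
#' position falls inside each interval.
#'
#' @param x A \linkS4class{CoverageTrack}.
#' @param which A \link[GenomicRanges]{GRanges} of query intervals.
#' @param ... Additional arguments passed to methods.
#' @return Numeric vector of RPKM values, one per interval.
#' @export
setGeneric("rpkm", function(x, which, ...) standardGeneric("rpkm"))

#' Summit-anchored 50 bp bin profiles around a break site
#'
#' @param x A \linkS4class{ReadEndSet} or \linkS4class{CoverageTrack}.
#' @param site A single-row \link[GenomicRanges]{GRanges} break site with a
#'   \code{summit} metadata column (0-based coordinate).
#' @param ... Additional arguments passed to methods.
#' @return A list with elements \code{left} and \code{right}, each a
#'   \linkS4class{BinProfile}.
#' @export
setGeneric("binProfile", function(x, site, ...) standardGeneric("binProfile"))

#' Maximum-endpoint resection calls for break sites
#'
#' @param x A \linkS4class{ReadEndSet} or \linkS4class{CoverageTrack}.
#' @param sites Break sites as a \link[GenomicRanges]{GRanges} with
#'   \code{site_id} and \code{summit} metadata columns.
#' @param ... Additional arguments passed to methods.
#' @return A data.frame of per-site resection calls.
#' @export
setGeneric("callResection", function(x, sites, ...) standardGeneric("callResection"))
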