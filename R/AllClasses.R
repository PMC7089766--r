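#' @include AllGenerics.R utils.R
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Nuclease and timepoint condition levels
#'
#' END-seq blunting cocktails and washout timepoints form closed vocabularies:
#' the ExoVII+ExoT combination detects both protein-linked and protein-free
#' double-strand-break ends, ExoT alone detects only protein-free ends; samples
#' are harvested before drug washout, immediately after washout, or after a
#' 2 hr recovery.
#'
#' @return Character vector of allowed levels.
#' @export
nucleaseLevels <- function() c("EXOVII_EXOT", "EXOT_ONLY")

#' @rdname nucleaseLevels
#' @export
timepointLevels <- function() c("PRE_WASHOUT", "WASHOUT_0H", "WASHOUT_2H")

## treatment labels interpreted as "no break-inducing drug"
.untreatedLabels <- c("NONE", "UNTREATED", "CONTROL", "CTRL", "MOCK")

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic END-seq generator
#'
#' Holds the genome layout and per-sample emission parameters shared by all
#' samples of a simulated experiment. Break-site and spike-in summits are
#' placed at least 10 kb apart and at least 5 kb from chromosome ends so that
#' resection flanks never overlap.
#'
#' @slot chromSizes Named numeric vector of chromosome lengths (bp).
#' @slot nSites Number of lesion sites.
#' @slot nSpikeSites Number of zinc-finger-nuclease spike-in sites.
#' @slot spikeInFraction Fraction of library cells that are spike-in cells
#'   (default 0.025, i.e. the 1:40 mixing ratio).
#' @slot cellsPerSample Cells contributing to each library.
#' @slot backgroundRate Expected noise read-ends per kb of genome.
#' @slot summitJitter Half-width (bp) of the blunting jitter around summits.
#' @slot washoutSurvival Per-lesion survival probability applied to
#'   protein-free and irreversible lesions at the 2 hr washout timepoint.
#' @slot seed Integer run-level seed; all randomness derives from it.
#' @export
setClass("SimConfig", representation(
    chromSizes = "numeric",
    nSites = "integer",
    nSpikeSites = "integer",
    spikeInFraction = "numeric",
    cellsPerSample = "integer",
    backgroundRate = "numeric",
    summitJitter = "integer",
    washoutSurvival = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (!.chromSizesOk(object@chromSizes))
        msg <- c(msg, "chromSizes must be a named numeric vector of positive lengths")
    if (object@nSites < 0L) msg <- c(msg, "nSites must be >= 0")
    if (object@nSpikeSites < 0L) msg <- c(msg, "nSpikeSites must be >= 0")
    if (object@spikeInFraction < 0 || object@spikeInFraction >= 1)
        msg <- c(msg, "spikeInFraction must be in [0, 1)")
    if (object@cellsPerSample < 1L) msg <- c(msg, "cellsPerSample must be >= 1")
    if (object@backgroundRate < 0) msg <- c(msg, "backgroundRate must be >= 0")
    if (object@summitJitter < 0L) msg <- c(msg, "summitJitter must be >= 0")
    if (object@washoutSurvival < 0 || object@washoutSurvival > 1)
        msg <- c(msg, "washoutSurvival must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig Constructor.
#' @param chromSizes,nSites,nSpikeSites,spikeInFraction,cellsPerSample,backgroundRate,summitJitter,washoutSurvival,seed
#'   See slot documentation.
#' @return A \code{SimConfig} object.
#' @export
simConfig <- function(chromSizes, nSites = 200L, nSpikeSites = 20L,
                      spikeInFraction = 0.025, cellsPerSample = 2000L,
                      backgroundRate = 0.05, summitJitter = 3L,
                      washoutSurvival = 0.5, seed = 1L) {
    new("SimConfig",
        chromSizes = chromSizes,
        nSites = .assertCount(nSites, "nSites"),
        nSpikeSites = .assertCount(nSpikeSites, "nSpikeSites"),
        spikeInFraction = spikeInFraction,
        cellsPerSample = .assertCount(cellsPerSample, "cellsPerSample", 1L),
        backgroundRate = backgroundRate,
        summitJitter = .assertCount(summitJitter, "summitJitter"),
        washoutSurvival = washoutSurvival,
        seed = .assertCount(seed, "seed"))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", length(object@chromSizes), "chromosome(s),",
        sum(object@chromSizes), "bp total\n")
    cat("  sites:", object@nSites, " spike-in sites:", object@nSpikeSites,
        sprintf(" spike fraction: %.3g", object@spikeInFraction), "\n")
    cat("  cells/sample:", object@cellsPerSample,
        " background:", object@backgroundRate, "reads/kb",
        " jitter: +/-", object@summitJitter, "bp\n")
    cat("  2h washout survival:", object@washoutSurvival,
        " seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# SampleMeta
# ---------------------------------------------------------------------------

#' Metadata for one END-seq sample
#'
#' @slot sampleId Sample identifier.
#' @slot treatment Free-text treatment label (e.g. \code{"ETO"},
#'   \code{"BTZ_pre_ETO"}); labels such as \code{"UNTREATED"} mark controls.
#' @slot nuclease One of \code{nucleaseLevels()}.
#' @slot timepoint One of \code{timepointLevels()}.
#' @slot spikeInFraction Spike-in cell fraction for this library.
#' @slot totalReads Library size; \code{NA} until populated.
#' @export
setClass("SampleMeta", representation(
    sampleId = "character",
    treatment = "character",
    nuclease = "character",
    timepoint = "character",
    spikeInFraction = "numeric",
    totalReads = "numeric"
))

setValidity("SampleMeta", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "sampleId must be a non-empty string")
    if (!object@nuclease %in% nucleaseLevels())
        msg <- c(msg, sprintf("unknown nuclease '%s' (allowed: %s)",
                              object@nuclease, paste(nucleaseLevels(), collapse = ", ")))
    if (!object@timepoint %in% timepointLevels())
        msg <- c(msg, sprintf("unknown timepoint '%s' (allowed: %s)",
                              object@timepoint, paste(timepointLevels(), collapse = ", ")))
    if (object@spikeInFraction < 0 || object@spikeInFraction >= 1)
        msg <- c(msg, "spikeInFraction must be in [0, 1)")
    if (!is.na(object@totalReads) && object@totalReads <= 0)
        msg <- c(msg, "totalReads must be > 0 once populated")
    if (length(msg)) msg else TRUE
})

#' @describeIn SampleMeta Constructor.
#' @param sampleId,treatment,nuclease,timepoint,spikeInFraction,totalReads
#'   See slot documentation.
#' @return A \code{SampleMeta} object.
#' @export
sampleMeta <- function(sampleId, treatment, nuclease, timepoint,
                       spikeInFraction = 0.025, totalReads = NA_real_) {
    new("SampleMeta", sampleId = sampleId, treatment = treatment,
        nuclease = nuclease, timepoint = timepoint,
        spikeInFraction = spikeInFraction, totalReads = totalReads)
}

#' Is a sample an untreated control?
#'
#' @param meta A \linkS4class{SampleMeta}.
#' @return \code{TRUE} when the treatment label marks an untreated control.
#' @export
isUntreated <- function(meta) toupper(meta@treatment) %in% .untreatedLabels

setMethod("show", "SampleMeta", function(object) {
    cat(sprintf("SampleMeta '%s': treatment=%s nuclease=%s timepoint=%s spike=%.3g reads=%s\n",
                object@sampleId, object@treatment, object@nuclease,
                object@timepoint, object@spikeInFraction,
                ifelse(is.na(object@totalReads), "NA", format(object@totalReads))))
})

# ---------------------------------------------------------------------------
# ReadEndSet
# ---------------------------------------------------------------------------

#' Positions and strands of sequenced DNA ends for one sample
#'
#' The raw END-seq observable: each record is a single 1 bp read-end position.
#' Stored as a width-1 \link[GenomicRanges]{GRanges} (1-based internally; BED
#' input/output converts to/from 0-based half-open).
#'
#' @slot reads Width-1 \code{GRanges} of read-end positions with strand.
#' @slot chromSizes Named numeric vector of chromosome lengths (bp); may be
#'   empty when unknown.
#' @export
setClass("ReadEndSet", representation(
    reads = "GRanges",
    chromSizes = "numeric"
))

setValidity("ReadEndSet", function(object) {
    msg <- character()
    if (length(object@reads) && any(GenomicRanges::width(object@reads) != 1L))
        msg <- c(msg, "all read ends must have width 1")
    if (length(object@chromSizes)) {
        if (!.chromSizesOk(object@chromSizes))
            msg <- c(msg, "chromSizes must be a named numeric vector")
        else if (length(object@reads)) {
            ch <- as.character(GenomicRanges::seqnames(object@reads))
            bad <- !ch %in% names(object@chromSizes)
            if (any(bad))
                msg <- c(msg, sprintf("read on unknown chromosome '%s'", ch[bad][1L]))
            else {
                sz <- object@chromSizes[ch]
                over <- GenomicRanges::end(object@reads) > sz
                if (any(over))
                    msg <- c(msg, sprintf("read beyond chromosome end at %s:%d",
                                          ch[over][1L],
                                          GenomicRanges::start(object@reads)[over][1L] - 1L))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ReadEndSet Constructor from a \code{GRanges} of width-1 ranges.
#' @param reads Width-1 \code{GRanges}.
#' @param chromSizes Optional named numeric vector of chromosome lengths.
#' @return A \code{ReadEndSet}.
#' @export
readEndSet <- function(reads, chromSizes = numeric()) {
    new("ReadEndSet", reads = reads, chromSizes = chromSizes)
}

#' @describeIn ReadEndSet Number of read ends.
#' @param x A \code{ReadEndSet}.
#' @export
setMethod("totalReads", "ReadEndSet", function(x) length(x@reads))

#' @describeIn ReadEndSet Chromosome sizes.
#' @export
setMethod("chromSizes", "ReadEndSet", function(x) x@chromSizes)

#' Underlying GRanges of a ReadEndSet
#'
#' @param x A \linkS4class{ReadEndSet}.
#' @return Width-1 \code{GRanges} of read-end positions.
#' @export
readEnds <- function(x) {
    stopifnot(is(x, "ReadEndSet"))
    x@reads
}

setMethod("show", "ReadEndSet", function(object) {
    cat("ReadEndSet:", length(object@reads), "read ends on",
        length(unique(as.character(GenomicRanges::seqnames(object@reads)))),
        "chromosome(s)\n")
})

# ---------------------------------------------------------------------------
# CoverageTrack
# ---------------------------------------------------------------------------

#' Binned read-end coverage for one sample
#'
#' Per-chromosome vectors of read-end counts in fixed-width bins, with the
#' library size retained so RPKM/RPM scalings can be computed on demand.
#' Strand-split counts are kept only when built with \code{stranded = TRUE}
#' (used by the stranded resection mode).
#'
#' @slot binWidth Bin width in bp.
#' @slot counts Named list, chromosome -> numeric vector of per-bin counts.
#' @slot countsPlus,countsMinus Strand-split counts (empty lists when
#'   unstranded).
#' @slot chromSizes Named numeric vector of chromosome lengths (bp).
#' @slot totalReads Library size (all read ends, genome-wide).
#' @export
setClass("CoverageTrack", representation(
    binWidth = "integer",
    counts = "list",
    countsPlus = "list",
    countsMinus = "list",
    chromSizes = "numeric",
    totalReads = "numeric"
))

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (object@binWidth < 1L) msg <- c(msg, "binWidth must be >= 1")
    if (!.chromSizesOk(object@chromSizes))
        msg <- c(msg, "chromSizes must be a named numeric vector")
    if (!identical(sort(names(object@counts)), sort(names(object@chromSizes))))
        msg <- c(msg, "counts must have one vector per chromosome")
    if (any(vapply(object@counts, function(v) any(v < 0), logical(1))))
        msg <- c(msg, "all bin counts must be >= 0")
    if (object@totalReads < 0) msg <- c(msg, "totalReads must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn CoverageTrack Bin width in bp.
#' @param x A \code{CoverageTrack}.
#' @export
setMethod("binWidth", "CoverageTrack", function(x) x@binWidth)

#' @describeIn CoverageTrack Library size.
#' @export
setMethod("totalReads", "CoverageTrack", function(x) x@totalReads)

#' @describeIn CoverageTrack Chromosome sizes.
#' @export
setMethod("chromSizes", "CoverageTrack", function(x) x@chromSizes)

#' Whether a CoverageTrack carries strand-split counts
#'
#' @param x A \linkS4class{CoverageTrack}.
#' @return Logical.
#' @export
isStranded <- function(x) {
    stopifnot(is(x, "CoverageTrack"))
    length(x@countsPlus) > 0L
}

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack:", object@binWidth, "bp bins on",
        length(object@counts), "chromosome(s);",
        format(object@totalReads), "reads",
        if (isStranded(object)) "(stranded)\n" else "\n")
})

# ---------------------------------------------------------------------------
# BinProfile
# ---------------------------------------------------------------------------

#' Summit-anchored 50 bp bin profile for one side of a break
#'
#' Fifty signal bins covering summit to 2.5 kb and fifty background bins
#' covering 2.5-5 kb on one side of a break summit, as RPKM. The maximum over
#' the background bins is the background level used by the resection caller.
#'
#' @slot siteId Site identifier.
#' @slot side \code{"LEFT"} or \code{"RIGHT"}.
#' @slot binWidth Bin width in bp (50).
#' @slot signalBins RPKM in bins 1..50 (summit to 2.5 kb).
#' @slot backgroundBins RPKM in bins 51..100 (2.5 kb to 5 kb).
#' @export
setClass("BinProfile", representation(
    siteId = "character",
    side = "character",
    binWidth = "integer",
    signalBins = "numeric",
    backgroundBins = "numeric"
))

setValidity("BinProfile", function(object) {
    msg <- character()
    if (!object@side %in% c("LEFT", "RIGHT"))
        msg <- c(msg, "side must be LEFT or RIGHT")
    if (length(object@signalBins) != 50L)
        msg <- c(msg, "exactly 50 signal bins required")
    if (length(object@backgroundBins) != 50L)
        msg <- c(msg, "exactly 50 background bins required")
    if (any(object@signalBins < 0) || any(object@backgroundBins < 0))
        msg <- c(msg, "bin values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn BinProfile Bin width in bp.
#' @param x A \code{BinProfile}.
#' @export
setMethod("binWidth", "BinProfile", function(x) x@binWidth)

#' Signal and background bins of a BinProfile
#'
#' @param x A \linkS4class{BinProfile}.
#' @return Numeric vector of 50 RPKM values.
#' @export
signalBins <- function(x) { stopifnot(is(x, "BinProfile")); x@signalBins }

#' @rdname signalBins
#' @export
backgroundBins <- function(x) { stopifnot(is(x, "BinProfile")); x@backgroundBins }

setMethod("show", "BinProfile", function(object) {
    cat(sprintf("BinProfile %s/%s: 50 x %d bp signal bins (max %.3g), background max %.3g\n",
                object@siteId, object@side, object@binWidth,
                max(object@signalBins), max(object@backgroundBins)))
})

# ---------------------------------------------------------------------------
# SpikeInStats
# ---------------------------------------------------------------------------

#' Spike-in normalization statistics
#'
#' RPKM of the zinc-finger-nuclease spike-in break windows, summarized by the
#' arithmetic mean, together with the spike-in cell fraction. Dividing a
#' peak's RPKM by \code{meanRpkm} and multiplying by
#' \code{100 * spikeInFraction} expresses signal as a cell-percentage.
#'
#' @slot perSiteRpkm RPKM over each spike-in summit window.
#' @slot meanRpkm Arithmetic mean of \code{perSiteRpkm}.
#' @slot spikeInFraction Fraction of library cells that are spike-in cells.
#' @export
setClass("SpikeInStats", representation(
    perSiteRpkm = "numeric",
    meanRpkm = "numeric",
    spikeInFraction = "numeric"
))

setValidity("SpikeInStats", function(object) {
    msg <- character()
    if (length(object@perSiteRpkm) < 1L)
        msg <- c(msg, "at least one spike-in site required")
    if (any(object@perSiteRpkm < 0)) msg <- c(msg, "spike RPKM must be >= 0")
    if (object@meanRpkm < 0) msg <- c(msg, "meanRpkm must be >= 0")
    if (object@spikeInFraction < 0 || object@spikeInFraction >= 1)
        msg <- c(msg, "spikeInFraction must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Mean spike-in RPKM
#'
#' @param x A \linkS4class{SpikeInStats}.
#' @return A single number.
#' @export
meanRpkm <- function(x) { stopifnot(is(x, "SpikeInStats")); x@meanRpkm }

#' @rdname meanRpkm
#' @export
spikeInFraction <- function(x) { stopifnot(is(x, "SpikeInStats")); x@spikeInFraction }

setMethod("show", "SpikeInStats", function(object) {
    cat(sprintf("SpikeInStats: %d site(s), mean RPKM %.4g, spike fraction %.3g (factor %.3g)\n",
                length(object@perSiteRpkm), object@meanRpkm,
                object@spikeInFraction, 100 * object@spikeInFraction))
})

# ---------------------------------------------------------------------------
# SpeciesFractions
# ---------------------------------------------------------------------------

#' Decomposition of TOP2-mediated DSB signal into lesion species
#'
#' Fractions of protein-free DSBs, reversible TOP2 cleavage complexes and
#' irreversible TOP2 cleavage complexes, relative to the initial (pre-washout,
#' ExoVII+ExoT) lesion pool. The three fractions sum to 1; the total TOP2cc
#' fraction is \code{1 - dsb}.
#'
#' @slot dsb Protein-free DSB fraction.
#' @slot reversible Reversible TOP2cc fraction.
#' @slot irreversible Irreversible TOP2cc fraction.
#' @slot nClamped Number of per-site values clamped into [0, 1] during
#'   estimation (quality-control counter).
#' @export
setClass("SpeciesFractions", representation(
    dsb = "numeric",
    reversible = "numeric",
    irreversible = "numeric",
    nClamped = "integer"
))

setValidity("SpeciesFractions", function(object) {
    msg <- character()
    v <- c(object@dsb, object@reversible, object@irreversible)
    if (any(v < 0) || any(v > 1)) msg <- c(msg, "fractions must be in [0, 1]")
    if (abs(sum(v) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1 (1e-9)")
    if (length(msg)) msg else TRUE
})

#' @describeIn SpeciesFractions Constructor.
#' @param dsb,reversible,irreversible Fractions in [0, 1] summing to 1.
#' @param nClamped QC counter of clamped per-site values.
#' @return A \code{SpeciesFractions}.
#' @export
speciesFractions <- function(dsb, reversible, irreversible, nClamped = 0L) {
    new("SpeciesFractions", dsb = dsb, reversible = reversible,
        irreversible = irreversible, nClamped = as.integer(nClamped))
}

#' Accessors for SpeciesFractions
#'
#' @param x A \linkS4class{SpeciesFractions}.
#' @return A single fraction.
#' @export
dsb <- function(x) { stopifnot(is(x, "SpeciesFractions")); x@dsb }

#' @rdname dsb
#' @export
reversibleTop2cc <- function(x) { stopifnot(is(x, "SpeciesFractions")); x@reversible }

#' @rdname dsb
#' @export
irreversibleTop2cc <- function(x) { stopifnot(is(x, "SpeciesFractions")); x@irreversible }

#' @rdname dsb
#' @export
totalTop2cc <- function(x) { stopifnot(is(x, "SpeciesFractions")); 1 - x@dsb }

setMethod("show", "SpeciesFractions", function(object) {
    cat(sprintf("SpeciesFractions: DSB %.3f | reversible TOP2cc %.3f | irreversible TOP2cc %.3f\n",
                object@dsb, object@reversible, object@irreversible))
    if (object@nClamped > 0L)
        cat("  (", object@nClamped, "per-site value(s) clamped during estimation )\n")
})
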