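#' @include AllClasses.R io.R
#' @importFrom stats rbinom rmultinom rexp rpois runif setNames median quantile
NULL

## minimum distance between summits and to chromosome ends; site placement
## uses a 15 kb grid with < 5 kb jitter so the 10 kb spacing holds exactly
.MIN_SPACING <- 10000L
.EDGE_MARGIN <- 5000L
.GRID_STEP <- 15000L

#' Construct a lesion truth table
#'
#' One row per break site: the probability a cell carries a TOP2-mediated DSB
#' there under treatment, the latent species mixture (reversible TOP2cc,
#' irreversible TOP2cc, protein-free DSB) and the resection length model for
#' protein-free lesions after washout. The three species fractions must sum
#' to 1; small deviations (< 1e-4, e.g. from rounding on file round-trips)
#' are renormalized, larger ones are an error.
#'
#' @param siteId,chrom,summit Site identifiers and 0-based summit positions.
#' @param pCleaved Per-cell cleavage probability in [0, 1].
#' @param fReversible,fIrreversible,fFree Species fractions.
#' @param resectionMeanBp Mean one-sided resection length (bp).
#' @param resectionMaxBp Hard cap on resection length (bp).
#' @return A data.frame with columns \code{site_id, chrom, summit, p_cleaved,
#'   f_reversible, f_irreversible, f_free, resection_mean_bp,
#'   resection_max_bp}.
#' @export
lesionTruth <- function(siteId, chrom, summit, pCleaved,
                        fReversible, fIrreversible, fFree,
                        resectionMeanBp, resectionMaxBp = 2500) {
    n <- length(siteId)
    df <- data.frame(site_id = siteId, chrom = chrom, summit = as.numeric(summit),
                     p_cleaved = rep_len(pCleaved, n),
                     f_reversible = rep_len(fReversible, n),
                     f_irreversible = rep_len(fIrreversible, n),
                     f_free = rep_len(fFree, n),
                     resection_mean_bp = rep_len(resectionMeanBp, n),
                     resection_max_bp = rep_len(resectionMaxBp, n),
                     stringsAsFactors = FALSE)
    if (any(df$p_cleaved < 0 | df$p_cleaved > 1))
        stop("p_cleaved must be in [0, 1]", call. = FALSE)
    s <- df$f_reversible + df$f_irreversible + df$f_free
    if (any(abs(s - 1) > 1e-4))
        stop("species fractions must sum to 1", call. = FALSE)
    df$f_reversible <- df$f_reversible / s
    df$f_irreversible <- df$f_irreversible / s
    df$f_free <- df$f_free / s
    if (any(df$resection_mean_bp < 0) ||
        any(df$resection_mean_bp > df$resection_max_bp))
        stop("need 0 <= resection_mean_bp <= resection_max_bp", call. = FALSE)
    df
}

.placementSlots <- function(chromSizes) {
    slots <- lapply(names(chromSizes), function(cn) {
        hi <- chromSizes[[cn]] - .EDGE_MARGIN - (.EDGE_MARGIN - 1L)
        if (hi < .EDGE_MARGIN) return(data.frame(chrom = character(),
                                                 pos = numeric()))
        data.frame(chrom = cn, pos = seq(.EDGE_MARGIN, hi, by = .GRID_STEP))
    })
    do.call(rbind, slots)
}

#' Simulate a genome of break sites and spike-in sites
#'
#' Places \code{nSites} lesion summits and \code{nSpikeSites}
#' zinc-finger-nuclease spike-in summits, all pairwise >= 10 kb apart and
#' >= 5 kb from chromosome ends, and attaches a \code{\link{lesionTruth}} row
#' to each lesion site. Deterministic given \code{config@seed}.
#'
#' Default truth parameters mirror an etoposide arm: 76% reversible TOP2cc,
#' 4% irreversible TOP2cc, 20% protein-free DSB, 20% of cells cleaved per
#' site, 500 bp mean resection capped at 2.5 kb.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param pCleaved,fReversible,fIrreversible,fFree,resectionMeanBp,resectionMaxBp
#'   Truth parameters, recycled across sites.
#' @return A list with \code{truth} (data.frame, see
#'   \code{\link{lesionTruth}}) and \code{spikeSites} (data.frame with
#'   \code{site_id, chrom, summit}).
#' @export
simulateGenome <- function(config, pCleaved = 0.2, fReversible = 0.76,
                           fIrreversible = 0.04, fFree = 0.20,
                           resectionMeanBp = 500, resectionMaxBp = 2500) {
    stopifnot(is(config, "SimConfig"))
    nTot <- config@nSites + config@nSpikeSites
    emptyTruth <- lesionTruth(character(), character(), numeric(), numeric(),
                              numeric(), numeric(), numeric(), numeric())
    if (nTot == 0L)
        return(list(truth = emptyTruth,
                    spikeSites = data.frame(site_id = character(),
                                            chrom = character(),
                                            summit = numeric())))
    slots <- .placementSlots(config@chromSizes)
    if (nrow(slots) < nTot)
        stop(sprintf(paste("chromosomes too short: %d candidate summit slots",
                           "available for %d requested sites at >= %d bp",
                           "spacing"), nrow(slots), nTot, .MIN_SPACING),
             call. = FALSE)
    withr::with_seed(config@seed, {
        pick <- slots[sample.int(nrow(slots), nTot), , drop = FALSE]
        jitter <- sample.int(.EDGE_MARGIN, nTot, replace = TRUE) - 1L
        pick$pos <- pick$pos + jitter
        lesion <- pick[seq_len(config@nSites), , drop = FALSE]
        spike <- pick[config@nSites + seq_len(config@nSpikeSites), , drop = FALSE]
        truth <- if (config@nSites > 0L)
            lesionTruth(sprintf("site_%03d", seq_len(config@nSites)),
                        lesion$chrom, lesion$pos, pCleaved,
                        fReversible, fIrreversible, fFree,
                        resectionMeanBp, resectionMaxBp)
        else emptyTruth
        spikeSites <- data.frame(
            site_id = if (config@nSpikeSites > 0L)
                sprintf("spike_%02d", seq_len(config@nSpikeSites)) else character(),
            chrom = as.character(spike$chrom), summit = as.numeric(spike$pos),
            stringsAsFactors = FALSE)
        list(truth = truth, spikeSites = spikeSites)
    })
}

## jittered blunt positions around a summit; strand follows the side
.emitBlunt <- function(n, summit, jitter) {
    if (n == 0L) return(data.frame(pos = numeric(), strand = character()))
    j <- if (jitter > 0L) sample.int(2L * jitter + 1L, n, replace = TRUE) -
             jitter - 1L else integer(n)
    str <- ifelse(j > 0, "+", ifelse(j < 0, "-",
                  sample(c("+", "-"), n, replace = TRUE)))
    data.frame(pos = summit + j, strand = str, stringsAsFactors = FALSE)
}

## resected positions: exponential one-sided distance, censored at the cap,
## side chosen left/right with probability 1/2 (strand tracks the side)
.emitResected <- function(n, summit, meanBp, maxBp) {
    if (n == 0L) return(data.frame(pos = numeric(), strand = character()))
    d <- if (meanBp > 0) pmin(round(rexp(n, rate = 1 / meanBp)), maxBp)
         else numeric(n)
    side <- sample(c(-1L, 1L), n, replace = TRUE)
    data.frame(pos = summit + side * d,
               strand = ifelse(side > 0, "+", "-"), stringsAsFactors = FALSE)
}

#' Simulate one END-seq sample
#'
#' Per cell and lesion site, a lesion is drawn with probability
#' \code{p_cleaved} and assigned a species by the site's mixture. A read end
#' is emitted iff the species is observable under the sample's nuclease and
#' timepoint: ExoVII+ExoT sees reversible TOP2ccs only before washout (they
#' re-ligate on washout) and irreversible TOP2ccs and protein-free DSBs at
#' any timepoint; ExoT alone sees only protein-free DSBs. At the 2 hr washout
#' timepoint surviving lesions are thinned by \code{config@washoutSurvival}.
#' Protein-free lesions at washout timepoints are displaced from the summit
#' by a censored-exponential resection length (left or right with probability
#' 1/2); all other emissions fall within \code{summitJitter} of the summit.
#' Spike-in sites emit from the spike-in cell fraction at full penetrance in
#' every sample, never resected. Uniform background reads are added at
#' \code{backgroundRate} per kb. Untreated-control samples emit no lesion
#' reads. Deterministic given the seed.
#'
#' @param truth Lesion truth table from \code{\link{simulateGenome}}.
#' @param spikeSites Spike-in site table from \code{\link{simulateGenome}}.
#' @param meta A \linkS4class{SampleMeta}.
#' @param config A \linkS4class{SimConfig}.
#' @param seed Integer seed; defaults to
#'   \code{deriveSampleSeed(config@seed, meta@sampleId)} so each sample is an
#'   independent reproducible draw.
#' @return A \linkS4class{ReadEndSet}.
#' @export
simulateSample <- function(truth, spikeSites, meta, config, seed = NULL) {
    stopifnot(is(meta, "SampleMeta"), is(config, "SimConfig"))
    validObject(meta)
    if (is.null(seed)) seed <- deriveSampleSeed(config@seed, meta@sampleId)
    treated <- !isUntreated(meta)
    nuc <- meta@nuclease
    tp <- meta@timepoint
    cells <- config@cellsPerSample
    jit <- config@summitJitter
    withr::with_seed(seed, {
        parts <- list()
        if (treated && nrow(truth) > 0L) {
            for (i in seq_len(nrow(truth))) {
                tr <- truth[i, ]
                nLesion <- rbinom(1L, cells, tr$p_cleaved)
                cnt <- as.vector(rmultinom(1L, nLesion,
                                           c(tr$f_reversible, tr$f_irreversible,
                                             tr$f_free)))
                nRev <- if (nuc == "EXOVII_EXOT" && tp == "PRE_WASHOUT")
                    cnt[1L] else 0L
                nIrr <- if (nuc == "EXOVII_EXOT") cnt[2L] else 0L
                nFree <- cnt[3L]
                if (tp == "WASHOUT_2H") {
                    nIrr <- rbinom(1L, nIrr, config@washoutSurvival)
                    nFree <- rbinom(1L, nFree, config@washoutSurvival)
                }
                nBlunt <- nRev + nIrr + if (tp == "PRE_WASHOUT") nFree else 0L
                nResect <- if (tp == "PRE_WASHOUT") 0L else nFree
                em <- rbind(.emitBlunt(nBlunt, tr$summit, jit),
                            .emitResected(nResect, tr$summit,
                                          tr$resection_mean_bp,
                                          tr$resection_max_bp))
                if (nrow(em)) {
                    em$chrom <- tr$chrom
                    parts[[length(parts) + 1L]] <- em
                }
            }
        }
        if (nrow(spikeSites) > 0L && meta@spikeInFraction > 0) {
            for (i in seq_len(nrow(spikeSites))) {
                n <- rbinom(1L, cells, meta@spikeInFraction)
                em <- .emitBlunt(n, spikeSites$summit[i], jit)
                if (nrow(em)) {
                    em$chrom <- spikeSites$chrom[i]
                    parts[[length(parts) + 1L]] <- em
                }
            }
        }
        if (config@backgroundRate > 0) {
            nBg <- rpois(1L, config@backgroundRate * sum(config@chromSizes) / 1000)
            if (nBg > 0L) {
                cn <- sample(names(config@chromSizes), nBg, replace = TRUE,
                             prob = config@chromSizes)
                pos <- floor(runif(nBg) * config@chromSizes[cn])
                parts[[length(parts) + 1L]] <- data.frame(
                    pos = pos, strand = sample(c("+", "-"), nBg, replace = TRUE),
                    chrom = cn, stringsAsFactors = FALSE)
            }
        }
        if (length(parts) == 0L) {
            gr <- GRanges()
        } else {
            em <- do.call(rbind, parts)
            em$pos <- pmin(pmax(em$pos, 0), config@chromSizes[em$chrom] - 1)
            o <- order(match(em$chrom, names(config@chromSizes)), em$pos, em$strand)
            em <- em[o, ]
            gr <- GRanges(em$chrom, IRanges(em$pos + 1, em$pos + 1),
                          strand = em$strand)
        }
        readEndSet(gr, chromSizes = config@chromSizes)
    })
}

# ---------------------------------------------------------------------------
# truth / sample-sheet round trips
# ---------------------------------------------------------------------------

#' Write and read a lesion truth table
#'
#' Tab-separated with a header; spike-in sites are carried in the same file,
#' marked by the \code{is_spike} column. Fractions are written with 6
#' decimals; \code{readTruth} renormalizes the species mixture so it sums to
#' 1 exactly after rounding.
#'
#' @param truth Truth table (see \code{\link{lesionTruth}}).
#' @param spikeSites Spike-in site table (\code{site_id, chrom, summit}).
#' @param path File path.
#' @return \code{writeTruth}: the path, invisibly. \code{readTruth}: a list
#'   with \code{truth} and \code{spikeSites}.
#' @export
writeTruth <- function(truth, spikeSites, path) {
    cols <- c("site_id", "chrom", "summit", "p_cleaved", "f_reversible",
              "f_irreversible", "f_free", "resection_mean_bp",
              "resection_max_bp", "is_spike")
    fmt <- function(df, spike) {
        if (nrow(df) == 0L) return(NULL)
        if (spike) {
            df <- data.frame(site_id = df$site_id, chrom = df$chrom,
                             summit = df$summit, p_cleaved = 0,
                             f_reversible = 0, f_irreversible = 0, f_free = 1,
                             resection_mean_bp = 0, resection_max_bp = 0,
                             is_spike = 1L)
        } else df$is_spike <- 0L
        df[cols]
    }
    out <- rbind(fmt(truth, FALSE), fmt(spikeSites, TRUE))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(cols, collapse = "\t"), con)
    if (!is.null(out) && nrow(out)) {
        lines <- sprintf("%s\t%s\t%d\t%.6f\t%.6f\t%.6f\t%.6f\t%g\t%g\t%d",
                         out$site_id, out$chrom, as.integer(out$summit),
                         out$p_cleaved, out$f_reversible, out$f_irreversible,
                         out$f_free, out$resection_mean_bp,
                         out$resection_max_bp, out$is_spike)
        writeLines(lines, con)
    }
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    spike <- df[df$is_spike == 1L, c("site_id", "chrom", "summit")]
    rownames(spike) <- NULL
    les <- df[df$is_spike == 0L, , drop = FALSE]
    truth <- lesionTruth(les$site_id, les$chrom, les$summit, les$p_cleaved,
                         les$f_reversible, les$f_irreversible, les$f_free,
                         les$resection_mean_bp, les$resection_max_bp)
    list(truth = truth, spikeSites = spike)
}

#' Write and read a sample sheet
#'
#' Tab-separated: \code{sample_id, treatment, nuclease, timepoint,
#' spike_in_fraction, reads_path}.
#'
#' @param metas List of \linkS4class{SampleMeta}.
#' @param readsPaths Character vector of read BED paths, one per sample.
#' @param path File path.
#' @return \code{writeSampleSheet}: the path, invisibly.
#'   \code{readSampleSheet}: a data.frame.
#' @export
writeSampleSheet <- function(metas, readsPaths, path) {
    stopifnot(length(metas) == length(readsPaths))
    df <- data.frame(
        sample_id = vapply(metas, function(m) m@sampleId, character(1)),
        treatment = vapply(metas, function(m) m@treatment, character(1)),
        nuclease = vapply(metas, function(m) m@nuclease, character(1)),
        timepoint = vapply(metas, function(m) m@timepoint, character(1)),
        spike_in_fraction = vapply(metas, function(m) m@spikeInFraction,
                                   numeric(1)),
        reads_path = readsPaths, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
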