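# small builders shared across tests

# ReadEndSet from 0-based positions
makeReads <- function(pos0, chrom = "chr1", strand = "+",
                      chromSizes = c(chr1 = 1e5)) {
    gr <- GenomicRanges::GRanges(rep_len(chrom, length(pos0)),
                                 IRanges::IRanges(pos0 + 1, pos0 + 1),
                                 strand = rep_len(strand, length(pos0)))
    readEndSet(gr, chromSizes = chromSizes)
}

# single break site as GRanges with an exactly bin-aligned interval
makeSite <- function(summit0, flank = 2500, chrom = "chr1", id = "s1") {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(summit0 - flank + 1,
                                                  summit0 + flank))
    S4Vectors::mcols(gr)$site_id <- id
    S4Vectors::mcols(gr)$summit <- summit0
    gr
}

# four-sample design (pre/0h ExoVII, 0h ExoT, untreated control) used by the
# recovery tests; returns signal matrix of spike-normalized cell percentages
simFourSamples <- function(cfg, gen, treatment = "ETO") {
    metas <- list(
        pre = sampleMeta("pre", treatment, "EXOVII_EXOT", "PRE_WASHOUT",
                         spikeInFraction = cfg@spikeInFraction),
        w0 = sampleMeta("w0", treatment, "EXOVII_EXOT", "WASHOUT_0H",
                        spikeInFraction = cfg@spikeInFraction),
        t0 = sampleMeta("t0", treatment, "EXOT_ONLY", "WASHOUT_0H",
                        spikeInFraction = cfg@spikeInFraction),
        ctrl = sampleMeta("ctrl", "UNTREATED", "EXOVII_EXOT", "PRE_WASHOUT",
                          spikeInFraction = cfg@spikeInFraction))
    reads <- lapply(metas, simulateSample, truth = gen$truth,
                    spikeSites = gen$spikeSites, config = cfg)
    tracks <- lapply(reads, coverageFromReads, binWidth = 50)
    sites <- breakSites(gen$truth$chrom, gen$truth$summit,
                        siteId = gen$truth$site_id,
                        chromSizes = cfg@chromSizes)
    spikes <- lapply(tracks, spikeInFactor, spikeSites = gen$spikeSites,
                     spikeInFraction = cfg@spikeInFraction)
    sig <- mapply(function(tr, sp) toCellPercentage(rpkm(tr, sites), sp),
                  tracks, spikes)
    rownames(sig) <- gen$truth$site_id
    list(sig = sig, reads = reads, tracks = tracks, sites = sites,
         spikes = spikes)
}
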