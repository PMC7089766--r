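test_that("fold-enrichment detection implements the >threshold rule", {
    # treated: 22 reads in the site window; control: 2; equal library sizes
    filler <- seq(50000, 99999, length.out = 978)
    trT <- coverageFromReads(makeReads(c(rep(10500, 22), round(filler))), 50)
    trC <- coverageFromReads(makeReads(c(rep(10500, 2), round(filler),
                                         round(seq(1, 977,
                                                   length.out = 20)))), 50)
    site <- makeSite(10500, flank = 500)
    det <- detectSites(trT, trC, site, foldThreshold = 10,
                       pseudocountRpkm = 0)
    expect_equal(det$fold, 11)                  # 22/2, depths equal
    expect_true(det$detected)

    det5 <- detectSites(trT, trC, site, foldThreshold = 10,
                        pseudocountRpkm = det$rpkm_control * 1.2)
    expect_false(det5$detected)                 # 11 / 2.2 = 5 < 10

    # zero control signal: pseudocount alone sets the denominator
    trC0 <- coverageFromReads(makeReads(round(filler)), 50)
    d0 <- detectSites(trT, trC0, site, foldThreshold = 10,
                      pseudocountRpkm = det$rpkm / 11)
    expect_equal(d0$fold, 11, tolerance = 1e-9)
    expect_true(d0$detected)

    expect_error(detectSites(trT, coverageFromReads(makeReads(1), 25), site),
                 "bin width")
})

test_that("spike-in statistics average window RPKM and reject zero signal", {
    # two spike summits with 101 and 202 reads; library 1000
    pos <- c(rep(10000, 101), rep(50000, 202),
             round(seq(80000, 99000, length.out = 697)))
    tr <- coverageFromReads(makeReads(pos), 50)
    spikes <- data.frame(site_id = c("sp1", "sp2"), chrom = "chr1",
                         summit = c(10000, 50000))
    st <- spikeInFactor(tr, spikes, windowBp = 5000)
    expect_equal(st@perSiteRpkm, c(20000, 40000))  # n / (5.05 kb * 1e-3 M)... lengths cancel below
    expect_equal(meanRpkm(st), mean(st@perSiteRpkm))

    # doubling depth leaves the mean unchanged
    tr2 <- coverageFromReads(makeReads(rep(pos, 2)), 50)
    expect_equal(meanRpkm(spikeInFactor(tr2, spikes, windowBp = 5000)),
                 meanRpkm(st), tolerance = 1e-12)

    far <- data.frame(site_id = "sp0", chrom = "chr1", summit = 30000)
    expect_error(spikeInFactor(tr, far, windowBp = 2000),
                 "zero spike-in signal")
    expect_error(spikeInFactor(tr, spikes[0, ]), "at least one")
})

test_that("cell-percentage conversion applies the 100 x fraction factor", {
    expect_equal(cellPercentageFactor(0.025), 2.5)
    expect_equal(cellPercentageFactor(0.1), 10)
    expect_error(cellPercentageFactor(0), "cannot anchor")

    st <- new("SpikeInStats", perSiteRpkm = c(2, 4), meanRpkm = 3,
              spikeInFraction = 0.025)
    expect_equal(toCellPercentage(3, st), 2.5)   # peak at the spike mean
    expect_equal(toCellPercentage(6, st), 5)
    expect_equal(toCellPercentage(0, st), 0)
})

test_that("cell percentages are invariant under library-depth doubling", {
    pos <- c(rep(10000, 80), rep(50000, 25),
             round(seq(70000, 99000, length.out = 200)))
    spikes <- data.frame(site_id = "sp", chrom = "chr1", summit = 50000)
    site <- makeSite(10000)
    cp <- function(p) {
        tr <- coverageFromReads(makeReads(p), 50)
        toCellPercentage(rpkm(tr, site), spikeInFactor(tr, spikes))
    }
    expect_equal(cp(pos), cp(rep(pos, 2)), tolerance = 1e-9)
})

test_that("site overlap matches summits greedily nearest-first", {
    a <- breakSites("chr1", c(10000, 20000, 30000), flank = 100)
    expect_equal(unname(overlapSites(a, a)), c(0, 3, 0))

    b <- breakSites("chr2", c(10000, 20000), flank = 100)
    expect_equal(unname(overlapSites(a, b)), c(3, 0, 2))

    a2 <- breakSites("chr1", c(100, 500), flank = 50)
    b2 <- breakSites("chr1", c(120, 5000), flank = 50)
    expect_equal(unname(overlapSites(a2, b2, maxSummitDistance = 200)),
                 c(1, 1, 1))
})

test_that("replicate correlation agrees with a first-principles Pearson", {
    a <- c(1, 2, 3)
    expect_equal(correlateReplicates(a, a), 1)
    expect_equal(correlateReplicates(a, -a), -1)
    b <- c(2, 4, 6.5)
    expect_equal(correlateReplicates(a, b), pearsonByHand(a, b))
    set.seed(7)
    x <- rnorm(50); y <- x + rnorm(50)
    expect_equal(correlateReplicates(x, y), pearsonByHand(x, y))
    expect_error(correlateReplicates(c(1, 1, 1), a), "zero variance")
    expect_error(correlateReplicates(1:2, 1:2), "length >= 3")
})

test_that("cell percentage recovers the cleaved-cell fraction on simulation", {
    cfg <- simConfig(chromSizes = c(chr1 = 2e6, chr2 = 2e6), nSites = 50,
                     cellsPerSample = 1000, seed = 7)
    gen <- simulateGenome(cfg, pCleaved = 0.2)
    sim <- simFourSamples(cfg, gen)
    m <- mean(sim$sig[, "pre"])
    # spike normalization noise is shared across sites; include it in the SE
    seSpike <- 20 * sqrt((1 - 0.025) / (cfg@nSpikeSites * 1000 * 0.025))
    seSites <- stats::sd(sim$sig[, "pre"]) / sqrt(50)
    expect_lt(abs(m - 20), 3 * sqrt(seSpike^2 + seSites^2))
})
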