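test_that("genome simulation respects spacing and is seed-deterministic", {
    cfg <- simConfig(chromSizes = c(c1 = 1e6), nSites = 50, nSpikeSites = 0,
                     seed = 3)
    gen <- simulateGenome(cfg)
    expect_equal(nrow(gen$truth), 50)
    d <- diff(sort(gen$truth$summit))
    expect_true(all(d >= 10000))
    expect_true(all(gen$truth$summit >= 5000 &
                    gen$truth$summit <= 1e6 - 5000))
    gen2 <- simulateGenome(cfg)
    expect_identical(gen, gen2)

    empty <- simulateGenome(simConfig(chromSizes = c(c1 = 1e6), nSites = 0,
                                      nSpikeSites = 0))
    expect_equal(nrow(empty$truth), 0)
    expect_equal(nrow(empty$spikeSites), 0)

    expect_error(simulateGenome(simConfig(chromSizes = c(c1 = 20000),
                                          nSites = 50, nSpikeSites = 0)),
                 "too short")
})

test_that("species observability follows the nuclease/timepoint contract", {
    cfg <- simConfig(chromSizes = c(c1 = 1e6), nSites = 5, nSpikeSites = 0,
                     cellsPerSample = 200, backgroundRate = 0, seed = 5)
    # fully reversible lesions vanish on washout
    genRev <- simulateGenome(cfg, pCleaved = 1, fReversible = 1,
                             fIrreversible = 0, fFree = 0)
    r <- simulateSample(genRev$truth, genRev$spikeSites,
                        sampleMeta("a", "ETO", "EXOVII_EXOT", "WASHOUT_0H"),
                        cfg)
    expect_equal(totalReads(r), 0)
    # ExoT-only sees protein-free ends only
    genLinked <- simulateGenome(cfg, pCleaved = 1, fReversible = 0.5,
                                fIrreversible = 0.5, fFree = 0)
    r <- simulateSample(genLinked$truth, genLinked$spikeSites,
                        sampleMeta("b", "ETO", "EXOT_ONLY", "PRE_WASHOUT"),
                        cfg)
    expect_equal(totalReads(r), 0)
    # degenerate distributions collapse onto the summit
    cfg0 <- simConfig(chromSizes = c(c1 = 1e6), nSites = 3, nSpikeSites = 0,
                      cellsPerSample = 100, backgroundRate = 0,
                      summitJitter = 0, seed = 5)
    genFree <- simulateGenome(cfg0, pCleaved = 1, fReversible = 0,
                              fIrreversible = 0, fFree = 1,
                              resectionMeanBp = 0)
    r <- simulateSample(genFree$truth, genFree$spikeSites,
                        sampleMeta("c", "ETO", "EXOVII_EXOT", "WASHOUT_0H"),
                        cfg0)
    pos0 <- GenomicRanges::start(readEnds(r)) - 1
    expect_setequal(unique(pos0), genFree$truth$summit)
    expect_equal(totalReads(r), 300)
})

test_that("sample simulation is byte-identical for identical seeds", {
    cfg <- simConfig(chromSizes = c(c1 = 2e5), nSites = 4, nSpikeSites = 2,
                     cellsPerSample = 300, seed = 9)
    gen <- simulateGenome(cfg)
    meta <- sampleMeta("rep", "ETO", "EXOVII_EXOT", "PRE_WASHOUT")
    f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
    writeBed(simulateSample(gen$truth, gen$spikeSites, meta, cfg), f1)
    writeBed(simulateSample(gen$truth, gen$spikeSites, meta, cfg), f2)
    expect_identical(readLines(f1), readLines(f2))
    # different sample ids draw independently
    meta2 <- sampleMeta("rep2", "ETO", "EXOVII_EXOT", "PRE_WASHOUT")
    r2 <- simulateSample(gen$truth, gen$spikeSites, meta2, cfg)
    expect_false(identical(readLines(f1),
                           readLines(writeBed(r2, tempfile()))))
})

test_that("emission counts follow the law of total emission", {
    cfg <- simConfig(chromSizes = c(c1 = 5e5), nSites = 10, nSpikeSites = 0,
                     cellsPerSample = 500, backgroundRate = 0, seed = 21)
    gen <- simulateGenome(cfg, pCleaved = 0.3, fReversible = 0.5,
                          fIrreversible = 0.1, fFree = 0.4)
    meta <- function(i) sampleMeta(paste0("s", i), "ETO", "EXOVII_EXOT",
                                   "PRE_WASHOUT")
    tot <- vapply(1:30, function(i)
        totalReads(simulateSample(gen$truth, gen$spikeSites, meta(i), cfg)),
        numeric(1))
    # all species observable pre-washout: expectation = sites * cells * p
    mu <- 10 * 500 * 0.3
    se <- sqrt(10 * 500 * 0.3 * 0.7 / 30)
    expect_lt(abs(mean(tot) - mu), 3 * se)
})

test_that("ExoVII+ExoT signal dominates ExoT-only signal pre-washout", {
    cfg <- simConfig(chromSizes = c(c1 = 3e5), nSites = 3, nSpikeSites = 0,
                     cellsPerSample = 200, backgroundRate = 0, seed = 13)
    gen <- simulateGenome(cfg, pCleaved = 0.5, fReversible = 0.4,
                          fIrreversible = 0.2, fFree = 0.4)
    both <- vapply(1:50, function(i)
        totalReads(simulateSample(gen$truth, gen$spikeSites,
            sampleMeta(paste0("v", i), "ETO", "EXOVII_EXOT", "PRE_WASHOUT"),
            cfg)), numeric(1))
    exoT <- vapply(1:50, function(i)
        totalReads(simulateSample(gen$truth, gen$spikeSites,
            sampleMeta(paste0("t", i), "ETO", "EXOT_ONLY", "PRE_WASHOUT"),
            cfg)), numeric(1))
    expect_gt(mean(both), mean(exoT))
})

test_that("spike-in sites emit at full penetrance from the spike fraction", {
    cfg <- simConfig(chromSizes = c(c1 = 5e5), nSites = 0, nSpikeSites = 8,
                     cellsPerSample = 2000, spikeInFraction = 0.025,
                     backgroundRate = 0, seed = 31)
    gen <- simulateGenome(cfg)
    r <- simulateSample(gen$truth, gen$spikeSites,
                        sampleMeta("sp", "UNTREATED", "EXOVII_EXOT",
                                   "PRE_WASHOUT"), cfg)
    n <- totalReads(r)
    mu <- 8 * 2000 * 0.025
    se <- sqrt(8 * 2000 * 0.025 * 0.975)
    expect_lt(abs(n - mu), 3 * se)
})

test_that("truth tables round-trip through disk", {
    cfg <- simConfig(chromSizes = c(c1 = 5e5), nSites = 6, nSpikeSites = 3,
                     seed = 2)
    gen <- simulateGenome(cfg, fReversible = 1 / 3, fIrreversible = 1 / 3,
                          fFree = 1 / 3)
    f <- tempfile(fileext = ".tsv")
    writeTruth(gen$truth, gen$spikeSites, f)
    back <- readTruth(f)
    expect_equal(back$spikeSites, gen$spikeSites)
    expect_equal(back$truth$summit, gen$truth$summit)
    # fractions rewritten with 6 decimals still sum to 1 within 1e-9
    s <- back$truth$f_reversible + back$truth$f_irreversible +
        back$truth$f_free
    expect_true(all(abs(s - 1) < 1e-9))

    f2 <- tempfile(fileext = ".tsv")
    writeTruth(gen$truth[0, ], gen$spikeSites[0, ], f2)
    expect_equal(length(readLines(f2)), 1L)  # header only
    back2 <- readTruth(f2)
    expect_equal(nrow(back2$truth), 0)
})

test_that("invalid metadata enums are rejected", {
    expect_error(sampleMeta("x", "ETO", "EXO_WRONG", "PRE_WASHOUT"),
                 "unknown nuclease")
    expect_error(sampleMeta("x", "ETO", "EXOT_ONLY", "LATER"),
                 "unknown timepoint")
    expect_error(lesionTruth("a", "c1", 100, 0.5, 0.5, 0.4, 0.4, 100),
                 "sum to 1")
})
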