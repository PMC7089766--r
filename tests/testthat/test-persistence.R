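test_that("persistence ratios follow the timepoint/initial definition", {
    expect_equal(persistenceRatio(4, 16), 0.25)
    expect_equal(persistenceRatio(7.3, 7.3), 1)
    expect_equal(persistenceRatio(16, 4), 4)    # gains reported, not clipped
    expect_error(persistenceRatio(1, 0), "initial signal")
})

test_that("fraction of initial breaks counts retained detections", {
    init <- sprintf("s%d", 1:100)
    expect_equal(fractionInitialBreaks(init, init[1:30]), 30)
    expect_equal(fractionInitialBreaks(init, init), 100)
    expect_equal(fractionInitialBreaks(init, c("x1", "x2")), 0)
    # sites appearing only at the timepoint do not inflate the fraction
    expect_equal(fractionInitialBreaks(init, c(init[1:10], "new1", "new2")),
                 10)
    expect_error(fractionInitialBreaks(character(), "s1"), "no initially")
})

test_that("persistence tables summarize per-site ratios per timepoint", {
    sig <- data.frame(initial = c(8, 4, 2), t0 = c(4, 2, 1),
                      t2 = c(2, 1, 0.5),
                      row.names = c("a", "b", "c"))
    pt <- persistenceTable(sig, initial = "initial")
    expect_equal(nrow(pt$records), 6)
    expect_equal(pt$summary$median, c(0.5, 0.25))
    expect_equal(pt$summary$n, c(3, 3))

    # a sample against itself is exactly 1 everywhere
    self <- persistenceTable(data.frame(initial = c(3, 5), again = c(3, 5)),
                             "initial")
    expect_true(all(self$records$persistence == 1))

    # missing / zero signal contributes ratio 0, not a dropped site
    sigNA <- data.frame(initial = c(10, 10), t0 = c(NA, 5),
                        row.names = c("a", "b"))
    ptNA <- persistenceTable(sigNA, "initial")
    expect_equal(ptNA$records$persistence, c(0, 0.5))

    # non-positive initial signal excludes the site with a warning
    sig0 <- data.frame(initial = c(0, 10), t0 = c(1, 5),
                       row.names = c("a", "b"))
    expect_warning(pt0 <- persistenceTable(sig0, "initial"), "excluded")
    expect_equal(pt0$records$site_id, "b")
})

test_that("persistence is invariant to common library-depth scaling", {
    sig <- data.frame(initial = c(8, 4, 2), t0 = c(4, 6, 1))
    for (k in c(0.5, 3, 1e6)) {
        a <- persistenceTable(sig, "initial")$records$persistence
        b <- persistenceTable(sig * k, "initial")$records$persistence
        expect_equal(a, b, tolerance = 1e-12)
    }
})

test_that("mean persistence recovers the washout survival on simulation", {
    s <- 0.3  # observable-lesion survival at 0 hr: the non-reversing share
    cfg <- simConfig(chromSizes = c(chr1 = 2e6), nSites = 60,
                     cellsPerSample = 1000, seed = 17)
    gen <- simulateGenome(cfg, pCleaved = 0.3, fReversible = 1 - s,
                          fIrreversible = 0, fFree = s)
    sim <- simFourSamples(cfg, gen)
    pt <- persistenceTable(data.frame(initial = sim$sig[, "pre"],
                                      WASHOUT_0H = sim$sig[, "w0"]),
                           "initial")
    m <- pt$summary$mean
    perSite <- stats::sd(pt$records$persistence) / sqrt(60)
    seSpike <- s * sqrt(2) *
        sqrt((1 - 0.025) / (cfg@nSpikeSites * 1000 * 0.025))
    expect_lt(abs(m - s), 3 * sqrt(perSite^2 + seSpike^2))
})
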