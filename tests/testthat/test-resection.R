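test_that("bin profiles anchor 50 bp bins at the summit", {
    cs <- c(chr1 = 1e5)
    rs <- makeReads(10120, chromSizes = cs)
    site <- makeSite(10000)
    prof <- binProfile(rs, site)
    expect_equal(which(signalBins(prof$right) > 0), 3)  # d in [100, 150)
    expect_true(all(signalBins(prof$left) == 0))

    # symmetric reads land in mirrored bins
    rs2 <- makeReads(c(10000 - 120, 10000 + 120), chromSizes = cs)
    prof2 <- binProfile(rs2, site)
    expect_equal(signalBins(prof2$left)[3], signalBins(prof2$right)[3])

    # conservation: bins account for every read within 5 kb of each side
    set.seed(3)
    pos <- 10000 + sample(-4999:4999, 300, replace = TRUE)
    rs3 <- makeReads(pos, chromSizes = cs)
    prof3 <- binProfile(rs3, site)
    toCount <- function(p) sum(c(signalBins(p), backgroundBins(p))) *
        (50 / 1000) * (totalReads(rs3) / 1e6)
    expect_equal(toCount(prof3$right) + toCount(prof3$left), 300)

    # stranded mode assigns minus-strand reads to the left profile
    rs4 <- makeReads(c(9800, 10200), strand = c("-", "+"), chromSizes = cs)
    ps <- binProfile(rs4, site, mode = "stranded")
    expect_equal(sum(signalBins(ps$left) > 0), 1)
    expect_equal(sum(signalBins(ps$right) > 0), 1)
    rs5 <- makeReads(c(9800, 10200), strand = c("+", "-"), chromSizes = cs)
    ps5 <- binProfile(rs5, site, mode = "stranded")
    expect_true(all(signalBins(ps5$left) == 0))
    expect_true(all(signalBins(ps5$right) == 0))

    expect_error(binProfile(rs, makeSite(3000)), "5 kb")
})

test_that("track-based profiles match read-based ones on aligned summits", {
    cs <- c(chr1 = 1e5)
    set.seed(8)
    pos <- 20000 + sample(-4999:4999, 400, replace = TRUE)
    rs <- makeReads(pos, chromSizes = cs)
    tr <- coverageFromReads(rs, binWidth = 50)
    site <- makeSite(20000)    # summit on the bin grid
    a <- binProfile(rs, site)
    b <- binProfile(tr, site)
    expect_equal(signalBins(a$right), signalBins(b$right))
    expect_equal(signalBins(a$left), signalBins(b$left))
    expect_equal(backgroundBins(a$left), backgroundBins(b$left))
})

test_that("background level is the maximum over background bins", {
    p <- new("BinProfile", siteId = "s", side = "RIGHT", binWidth = 50L,
             signalBins = rep(0, 50), backgroundBins = rep(0, 50))
    expect_equal(backgroundLevel(p), 0)
    bg <- c(rep(0.1, 49), 0.9)
    p@backgroundBins <- bg
    expect_equal(backgroundLevel(p), 0.9)
    p@backgroundBins <- sample(bg)
    expect_equal(backgroundLevel(p), 0.9)
})

test_that("the sliding-window endpoint scan matches its worked examples", {
    bins <- c(rep(5, 12), rep(0.5, 38))
    expect_equal(maxResectionEndpoint(bins, background = 1), 600)
    expect_equal(maxResectionEndpoint(rep(0.5, 50), background = 1), 0)
    expect_equal(maxResectionEndpoint(rep(5, 50), background = 1), 2500)
})

test_that("the endpoint scan agrees with a brute-force enumerator", {
    set.seed(19)
    for (i in 1:300) {
        kind <- i %% 3
        bins <- if (kind == 0) runif(50, 0, 2)
                else if (kind == 1) pmax(rexp(50, 1 / exp(-(1:50) / 15)), 0)
                else c(runif(12, 1, 5), runif(38, 0, 1.2))
        bg <- sample(c(0, 0.5, 1, quantile(bins, 0.6)), 1)
        expect_equal(maxResectionEndpoint(bins, background = bg),
                     bruteEndpoint(bins, bg))
    }
})

test_that("endpoints stay bounded, scale-invariant and monotone", {
    set.seed(23)
    for (i in 1:100) {
        bins <- runif(50, 0, 3)
        bg <- runif(1, 0, 2)
        e <- maxResectionEndpoint(bins, background = bg)
        expect_gte(e, 0); expect_lte(e, 2500)
        for (k in c(0.01, 7)) {
            expect_equal(maxResectionEndpoint(k * bins, background = k * bg),
                         e)
        }
        j <- sample.int(50, 1)
        up <- bins; up[j] <- up[j] + runif(1, 0, 3)
        expect_gte(maxResectionEndpoint(up, background = bg), e)
    }
})

test_that("resection calls combine per-side endpoints and the >100 bp rule", {
    cs <- c(chr1 = 1e5)
    # right side resected out to ~600 bp, left side quiet
    rs <- makeReads(c(10000 + rep(seq(0, 590, by = 10), 3), 9950),
                    chromSizes = cs)
    site <- makeSite(10000)
    rc <- callResection(rs, site)
    expect_equal(rc$endpoint_right, 600)
    expect_lte(rc$endpoint_left, 100)
    expect_equal(rc$max_endpoint, 600)
    expect_true(rc$resected)

    # endpoints of exactly 100 bp do not qualify (strict >)
    rs2 <- makeReads(c(10010, 10060, 9990, 9940), chromSizes = cs)
    rc2 <- callResection(rs2, site)
    expect_equal(rc2$max_endpoint, 100)
    expect_false(rc2$resected)

    # sites too close to a chromosome end are skipped with a warning
    sites <- c(makeSite(10000), makeSite(2000, id = "s2"))
    expect_warning(rc3 <- callResection(rs, sites), "skipped")
    expect_equal(nrow(rc3), 1)
})

test_that("deterministic 400 bp resection is recovered within one bin", {
    cfg <- simConfig(chromSizes = c(chr1 = 1e6), nSites = 10, nSpikeSites = 0,
                     cellsPerSample = 800, backgroundRate = 0,
                     summitJitter = 0, seed = 29)
    gen <- simulateGenome(cfg, pCleaved = 1, fReversible = 0,
                          fIrreversible = 0, fFree = 1,
                          resectionMeanBp = 400, resectionMaxBp = 400)
    r <- simulateSample(gen$truth, gen$spikeSites,
                        sampleMeta("x", "ETO", "EXOVII_EXOT", "WASHOUT_0H"),
                        cfg)
    sites <- breakSites(gen$truth$chrom, gen$truth$summit,
                        siteId = gen$truth$site_id,
                        chromSizes = cfg@chromSizes)
    rc <- callResection(r, sites)
    expect_true(all(abs(rc$max_endpoint - 400) <= 50))
})

test_that("stratification splits persistence by resected status", {
    calls <- data.frame(site_id = c("a", "b", "c", "d"),
                        resected = c(TRUE, TRUE, FALSE, FALSE))
    pers <- data.frame(site_id = c("a", "b", "c", "d"),
                       persistence = c(0.8, 0.6, 0.2, 0.4))
    st <- stratifyByResection(calls, pers)
    expect_equal(st$summary$n, c(2, 2))
    expect_equal(st$summary$median, c(0.7, 0.3))

    allRes <- stratifyByResection(
        data.frame(site_id = c("a", "b"), resected = TRUE), pers)
    expect_equal(allRes$summary$n, c(2, 0))
    expect_true(is.na(allRes$summary$median[2]))

    same <- stratifyByResection(calls,
        data.frame(site_id = c("a", "b", "c", "d"),
                   persistence = rep(0.5, 4)))
    expect_equal(same$summary$median[1], same$summary$median[2])
})
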