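test_that("expected window methylation evaluates the per-N line", {
    tab <- identityCalibration(25)
    expect_equal(expectedWindowMethylation(tab, 10, 0.2), 0.2)
    tab@table$slope <- rep(0.8, 23)
    tab@table$intercept <- rep(0.01, 23)
    expect_equal(expectedWindowMethylation(tab, 7, 0.10), 0.09)
    # negative prediction clamps to epsilon, staying a valid binomial p
    tab@table$slope <- rep(-0.5, 23)
    tab@table$intercept <- rep(0, 23)
    expect_equal(expectedWindowMethylation(tab, 7, 0.1), 1e-6)
    expect_error(expectedWindowMethylation(tab, 2, 0.1), "3..25")
    expect_error(expectedWindowMethylation(tab, 26, 0.1), "3..25")
})

test_that("expected methylation is monotone in read methylation when slope >= 0", {
    tab <- identityCalibration(25)
    set.seed(4)
    tab@table$slope <- runif(23, 0, 1.3)
    tab@table$intercept <- runif(23, -0.05, 0.05)
    for (N in c(3, 10, 25)) {
        m <- seq(0, 1, by = 0.05)
        p <- expectedWindowMethylation(tab, rep(N, length(m)), m)
        expect_true(all(diff(p) >= 0))
    }
})

test_that("unbiased control fits slope ~1 and intercept ~0", {
    sc <- SimConfig(seed = 2, genomeLength = 50000L,
        readMethMedian = 0.195, readMethSdlog = 0.5)
    g <- simulateGenome(sc)
    ctl <- simulateGdnaReads(sc, g$genome, 3000)
    tab <- fitCalibration(ctl, g$genome)
    mid <- tab@table$N %in% 10:20  # well-populated rows
    expect_true(all(abs(tab@table$slope[mid] - 1) < 0.05))
    expect_true(all(abs(tab@table$intercept[mid]) < 0.01))
    expect_identical(nrow(tab@table), 23L)  # one row per N = 3..25
})

test_that("a monotone AT bias yields decreasing slopes over high N", {
    sc <- SimConfig(seed = 3, genomeLength = 50000L,
        readMethMedian = 0.195, readMethSdlog = 0.5,
        atBiasModel = linearATBias(slopePerN = -0.025))
    g <- simulateGenome(sc)
    ctl <- simulateGdnaReads(sc, g$genome, 4000)
    tab <- fitCalibration(ctl, g$genome)
    k <- tab@table$slope[tab@table$N %in% 14:23]
    # generator expectation: slope proportional to the linear bias, so
    # fitted slopes decline with N; allow fit noise via a trend test
    expect_lt(stats::coef(stats::lm(k ~ seq_along(k)))[2], 0)
    expect_lt(tab@table$slope[tab@table$N == 22],
        tab@table$slope[tab@table$N == 14])
})

test_that("fit range endpoints are inclusive", {
    g <- randomGenome(3000, at = 0.6, seed = 8)
    set.seed(8)
    codes <- as.integer(g[[1]])
    atpos <- which(codes == 1L | codes == 8L)
    # one read at exactly 41% methylation: must enter the fit
    mk <- function(st, frac, id) {
        span <- atpos[atpos >= st & atpos <= st + 999L]
        k <- if (frac <= 0.2) ceiling(frac * length(span))
            else floor(frac * length(span))
        p <- span[seq_len(k)]
        MethylReadSet(id, "chrT", st, st + 999L, 99, list(p),
            list(ifelse(codes[p] == 1L, "+", "-")), g)
    }
    specs <- list(mk(1L, 0.07, "lo"), mk(1001L, 0.2, "mid"),
        mk(1L, 0.41, "hi"), mk(1001L, 0.5, "out"))
    rs <- MethylReadSet(
        vapply(specs, moleculeId, ""), rep("chrT", 4),
        vapply(specs, function(r) start(granges(r)), 1L),
        vapply(specs, function(r) end(granges(r)), 1L), rep(99, 4),
        lapply(specs, function(r) as.integer(m6aPositions(r)[[1]])),
        lapply(specs, function(r)
            ifelse(r@m6aStrand[[1]] == 1L, "-", "+")), g)
    expect_equal(avgMethylation(rs)[3], 0.41, tolerance = 0.005)
    # a read beyond the range alone cannot support a fit
    expect_error(fitCalibration(rs[4], g), "no control reads")
    # both endpoint reads count: three in-range methylation bins exist
    # only if 7% and 41% are included, and three bins is exactly what a
    # per-N fit needs
    expect_error(fitCalibration(rs, g), NA)
})

test_that("calibration recovers generator parameters within tolerance", {
    bias <- linearATBias(slopePerN = -0.02)
    # homogeneous composition so every read sees the same mean bias and
    # the analytic slope expectation bias(N) / (genome mean bias) holds
    sc <- SimConfig(seed = 13, genomeLength = 50000L, atBlockSd = 0,
        readMethMedian = 0.195, readMethSdlog = 0.5,
        atBiasModel = bias)
    g <- simulateGenome(sc)
    ctl <- simulateGdnaReads(sc, g$genome, 10000)
    tab <- fitCalibration(ctl, g$genome)
    ctx <- m6Afootprint:::.detectionContext(g$genome, sc)[[1]]
    gbar <- mean(bias[ctx$atc[ctx$at] + 1])
    mid <- tab@table$N %in% 10:20  # well-populated at 60% AT
    expect_true(all(abs(tab@table$slope[mid] -
        bias[tab@table$N[mid] + 1] / gbar) < 0.05))
    expect_true(all(abs(tab@table$intercept[mid]) < 0.01))
})

test_that("calibration table serialises and round-trips", {
    tab <- identityCalibration(25)
    path <- tempfile(fileext = ".tsv")
    writeCalibrationTable(tab, path)
    back <- readCalibrationTable(path)
    expect_equal(back@table$slope, tab@table$slope)
    expect_identical(back@windowSize, 25L)
    expect_equal(back@fitRange, c(0, 1))
})

test_that("poly(A) run assignment follows maximal same-strand runs", {
    # CACAC: every A is a run of 1; AAAA: all four in the run-4 bin
    g1 <- tinyGenome("CACACGGGGG")
    r1 <- mkRead(g1, 1, 10)
    prof1 <- polyABiasProfile(r1, g1)
    expect_identical(prof1$nAdenines[1], 2)
    expect_identical(sum(prof1$nAdenines), 2)
    g2 <- tinyGenome("AAAAGGGGGG")
    prof2 <- polyABiasProfile(mkRead(g2, 1, 10), g2)
    expect_identical(prof2$nAdenines[4], 4)
    expect_identical(sum(prof2$nAdenines), 4)
})

test_that("poly(A) detection bias is recovered in the profile", {
    polyA <- c(1, 1, 1, rep(0.5, 5))  # halved detection for runs >= 4
    sc <- SimConfig(seed = 6, genomeLength = 50000L,
        readMethDistribution = "fixed", readMethFixed = 0.3,
        polyABiasModel = polyA)
    g <- simulateGenome(sc)
    ctl <- simulateGdnaReads(sc, g$genome, 800)
    prof <- polyABiasProfile(ctl, g$genome)
    ratio <- prof$m6aFraction[4] / prof$m6aFraction[1]
    # 3-SE tolerance on the binomial fractions
    se <- sqrt(prof$m6aFraction[4] * (1 - prof$m6aFraction[4]) /
        prof$nAdenines[4]) / prof$m6aFraction[1]
    expect_lt(abs(ratio - 0.5), 3 * se + 0.02)
})

test_that("threshold calibration controls held-out false positives", {
    sc <- SimConfig(seed = 10, genomeLength = 50000L,
        readMethMedian = 0.11, readMethSdlog = 0.5)
    g <- simulateGenome(sc)
    ctl <- simulateGdnaReads(sc, g$genome, 600)
    half <- seq_len(300)
    tab <- fitCalibration(ctl[half], g$genome)
    thr <- calibrateThresholds(ctl[half], g$genome, tab,
        targetFpRate = 0.01)
    expect_s4_class(thr, "ThresholdPair")
    tr <- callReads(ctl[-half], g$genome, tab, thr)
    lab <- unlist(lapply(seq_len(length(tr)), function(i)
        as.character(stateLabels(tr)[[i]])))
    fp <- mean(lab == "N")
    expect_lt(fp, 0.01 + 3 * sqrt(0.01 * 0.99 / 300))
})

test_that("threshold calibration edge cases behave", {
    sc <- SimConfig(seed = 10, genomeLength = 30000L,
        readMethMedian = 0.11, readMethSdlog = 0.5)
    g <- simulateGenome(sc)
    ctl <- simulateGdnaReads(sc, g$genome, 100)
    tab <- identityCalibration(25)
    thr <- calibrateThresholds(ctl, g$genome, tab, targetFpRate = 1.0,
        grid = c(0.5, 0.9))
    expect_equal(thr@thresholdNucleosomal, 0.9)
    expect_error(calibrateThresholds(ctl[0], g$genome, tab),
        "empty control")
})
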