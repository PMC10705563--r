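test_that("window scan geometry and closed-form binomial tails", {
    g <- tinyGenome(strrep("A", 25))
    r <- mkRead(g, 1, 25)
    st <- scanWindows(r, g, identityCalibration())
    expect_identical(nrow(st), 1L)
    expect_identical(st$center, 13L)  # offset 12 from the read start
    expect_identical(st$nAdenines, 25L)
    # n = 10, pExp = 0.2, k = 0: pLow = 0.8^10, pHigh = 1.
    # first window holds 10 unmethylated adenines; 4 of the 20 read
    # adenines are methylated elsewhere, so read methylation is 0.2
    g2 <- tinyGenome(paste0(strrep("A", 10), strrep("GC", 20),
        strrep("A", 10)))
    tab <- identityCalibration(25)
    r2 <- mkRead(g2, 1, 60, c("51:+", "52:+", "53:+", "54:+"))
    expect_equal(avgMethylation(r2), 0.2)
    st2 <- scanWindows(r2, g2, tab)
    w <- st2[1, ]  # window 1..25: n = 10, k = 0
    expect_identical(w$nAdenines, 10L)
    expect_equal(w$pExp, 0.2)
    expect_equal(w$pLow, 0.8^10, tolerance = 1e-12)
    expect_equal(w$pHigh, 1)
})

test_that("fully methylated window has pHigh = pExp^n and pLow = 1", {
    g <- tinyGenome(paste0(strrep("GC", 11), "AAA", strrep("GC", 11)))
    r <- mkRead(g, 1, 47, c("23:+", "24:+", "25:+"))
    tab <- identityCalibration(25)
    st <- scanWindows(r, g, tab)
    w <- st[st$center == 24, ]
    expect_identical(w$nAdenines, 3L)
    expect_identical(w$kM6A, 3L)
    pexp <- expectedWindowMethylation(tab, 3, avgMethylation(r))
    expect_equal(w$pHigh, pexp^3, tolerance = 1e-12)
    expect_equal(w$pLow, 1)
})

test_that("both one-tailed p-values match brute-force pmf summation", {
    set.seed(77)
    for (i in 1:2000) {
        n <- sample(3:25, 1)
        k <- sample(0:n, 1)
        p <- runif(1, 1e-6, 1 - 1e-6)
        lo <- sum(dbinom(0:k, n, p))
        hi <- sum(dbinom(k:n, n, p))
        expect_lt(abs(pbinom(k, n, p) - lo), 1e-10)
        expect_lt(abs(pbinom(k - 1, n, p, lower.tail = FALSE) - hi),
            1e-10)
    }
    # the identity both tails must satisfy: pLow + pHigh = 1 + P(X = k)
    g <- randomGenome(200, at = 0.6, seed = 77)
    r <- methylateByTruth(g, 1, rep("A", 200), pAcc = 0.3)
    st <- scanWindows(r, g, identityCalibration())
    ok <- st$testable
    expect_equal(st$pLow[ok] + st$pHigh[ok],
        1 + dbinom(st$kM6A[ok], st$nAdenines[ok], st$pExp[ok]),
        tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(0.5, 7)), rep(0.5, 7))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    bruteBH <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- numeric(m)
        for (i in seq_len(m)) {
            j <- which(o == i)  # rank of p[i]
            adj[i] <- min(pmin(p[o][j:m] * m / (j:m), 1))
        }
        adj
    }
    set.seed(3)
    for (rep in 1:200) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
    }
})

test_that("state assignment applies thresholds and the tie rule", {
    thr <- ThresholdPair(0.853, 0.918)
    mkStats <- function(al, ah) data.frame(center = 13L,
        nAdenines = 10L, kM6A = 2L, pExp = 0.2, pLow = al, pHigh = ah,
        testable = TRUE, pAdjLow = al, pAdjHigh = ah)
    lab <- assignStates(mkStats(0.99, 0.01), thr, 1L, 25L)
    expect_identical(lab[13], "A")
    expect_identical(lab[1], "X")  # edge bases stay ambiguous
    expect_identical(assignStates(mkStats(0.5, 0.99), thr, 1L, 25L)[13],
        "N")
    # both pass: smaller adjusted p wins; exact tie is ambiguous
    expect_identical(assignStates(mkStats(0.2, 0.1), thr, 1L, 25L)[13],
        "A")
    expect_identical(assignStates(mkStats(0.1, 0.2), thr, 1L, 25L)[13],
        "N")
    expect_identical(assignStates(mkStats(0.6, 0.6), thr, 1L, 25L)[13],
        "X")
    expect_error(assignStates(mkStats(0.5, 0.5)[, -8], thr, 1L, 25L),
        "pAdjLow")
})

test_that("boundary resolution follows the stated rules in order", {
    # accessible extension then short-ambiguous reassignment
    lab <- resolveBoundaries(expandLab("A30 X20 N30"))
    expect_identical(paste(rle(lab)$values, collapse = ""), "AN")
    expect_identical(rle(lab)$lengths, c(42L, 38L))
    # overlapping extensions resolve to nucleosomal
    lab2 <- resolveBoundaries(expandLab("A30 X5 N5 X5 A30"))
    expect_identical(lab2[41:42], c("N", "N"))
    expect_identical(lab2[31:35], rep("A", 5))
    # a track without transitions is unchanged
    allA <- rep("A", 50)
    expect_identical(resolveBoundaries(allA), allA)
})

test_that("boundary resolution is idempotent and never flips called states", {
    set.seed(12)
    for (i in 1:300) {
        lab <- sample(c("A", "N", "X"), sample(30:200, 1),
            replace = TRUE, prob = c(0.4, 0.4, 0.2))
        r1 <- resolveBoundaries(lab)
        expect_identical(resolveBoundaries(r1), r1)
        # called bases are only consumed from ambiguous, never flipped
        expect_true(all(r1[lab == "A"] == "A"))
        expect_true(all(r1[lab == "N"] == "N"))
    }
})

test_that("reads with no m6A receive no accessible calls", {
    g <- randomGenome(300, at = 0.6, seed = 5)
    r <- mkRead(g, 1, 300)
    tr <- callReads(r, g, identityCalibration())
    expect_false(any(as.character(stateLabels(tr)[[1]]) == "A"))
})

test_that("a single footprint is recovered at about its true length", {
    set.seed(31)
    g <- randomGenome(600, at = 0.6, seed = 31)
    truth <- expandLab("A200 N147 A200")
    lens <- integer(0)
    mids <- numeric(0)
    for (i in 1:30) {
        r <- methylateByTruth(g, 1, truth, pAcc = 0.3)
        tr <- callReads(r, g, identityCalibration())
        lab <- as.character(stateLabels(tr)[[1]])
        rr <- rle(lab)
        e <- cumsum(rr$lengths)
        s <- e - rr$lengths + 1L
        j <- which(rr$values == "N")
        if (!length(j)) next
        j <- j[which.max(rr$lengths[j])]
        lens <- c(lens, rr$lengths[j])
        mids <- c(mids, (s[j] + e[j]) / 2)
    }
    expect_gt(length(lens), 25)
    expect_lt(abs(median(lens) - 147), 13)       # half-window tolerance
    expect_lt(abs(median(mids) - 273.5), 13)     # centered on truth
})

test_that("short reads pass through fully ambiguous with a message", {
    g <- tinyGenome(strrep("AT", 10))
    r <- mkRead(g, 1, 20)
    expect_message(tr <- callReads(r, g, identityCalibration()),
        "ambiguous")
    expect_true(all(as.character(stateLabels(tr)[[1]]) == "X"))
})

test_that("footprint length histogram counts nucleosomal runs", {
    t1 <- mkTrack(expandLab("A20 N147 A33"))
    h <- footprintLengths(t1)
    expect_identical(h$length, 147L)
    expect_identical(h$count, 1L)
    expect_equal(h$perMillionNt, 1 / (200 / 1e6))
    t2 <- mkTrack(rep("A", 50))
    expect_identical(nrow(footprintLengths(t2)), 0L)
})

test_that("ambiguous fraction decreases through boundary resolution", {
    sc <- SimConfig(seed = 17, genomeLength = 30000L,
        readMethDistribution = "fixed", readMethFixed = 0.12)
    g <- simulateGenome(sc)
    sim <- simulateNucleiReads(sc, g$genome, nReads = 60)
    cache <- m6Afootprint:::.adjustedCache(sim$reads, g$genome,
        identityCalibration(), 25L)
    thr <- ThresholdPair()
    ambBefore <- ambAfter <- 0
    tot <- 0
    for (e in cache) {
        raw <- rep("X", e$L)
        acc <- e$adjHigh < thr@thresholdAccessible
        nuc <- e$adjLow < thr@thresholdNucleosomal
        s <- ifelse(acc & !nuc, "A", ifelse(nuc & !acc, "N",
            ifelse(acc & nuc, ifelse(e$adjHigh < e$adjLow, "A",
                ifelse(e$adjLow < e$adjHigh, "N", "X")), "X")))
        raw[e$centers - e$start + 1L] <- s
        res <- resolveBoundaries(raw)
        ambBefore <- ambBefore + sum(raw == "X")
        ambAfter <- ambAfter + sum(res == "X")
        tot <- tot + e$L
    }
    expect_lt(ambAfter, ambBefore)
})

test_that("window size has only minor effects on the nucleosomal fraction", {
    sc <- SimConfig(seed = 19, genomeLength = 30000L,
        readMethDistribution = "fixed", readMethFixed = 0.12)
    g <- simulateGenome(sc)
    sim <- simulateNucleiReads(sc, g$genome, nReads = 60)
    fracs <- vapply(c(15L, 20L, 25L, 30L), function(W) {
        tr <- callReads(sim$reads, g$genome, identityCalibration(W),
            windowSize = W)
        lab <- unlist(lapply(seq_len(length(tr)), function(i)
            as.character(stateLabels(tr)[[i]])))
        mean(lab == "N")
    }, numeric(1))
    expect_lt(max(fracs) - min(fracs), 0.05)
})
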