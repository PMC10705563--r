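mkGenes <- function(starts, ends, strands, ids = NULL,
        chrom = "chrT") {
    gr <- GRanges(chrom, IRanges(starts, ends), strand = strands)
    mcols(gr)$gene_id <- if (is.null(ids))
        sprintf("g%02d", seq_along(gr)) else ids
    gr
}

test_that("phasing gene selection enforces overlap, length and promoter", {
    genes <- mkGenes(
        starts = c(1000, 1499, 3000, 5000, 7000),
        ends = c(1500, 2000, 3100, 5600, 7600),
        strands = c("+", "+", "+", "+", "-"),
        ids = c("ovl1", "ovl2", "short", "ok_plus", "ok_minus"))
    sel <- selectPhasingGenes(genes)
    # the two 1-bp overlappers are both removed; the 101-bp gene fails
    # the length filter; both isolated 601-bp genes survive
    expect_setequal(mcols(sel)$gene_id, c("ok_plus", "ok_minus"))
    # a gene whose upstream neighbour encroaches on the promoter fails
    genes2 <- mkGenes(c(1000, 1600), c(1500, 2200), c("+", "+"),
        c("up", "down"))
    expect_false("down" %in%
        mcols(selectPhasingGenes(genes2))$gene_id)
    # same geometry with a 200-bp clear promoter passes
    genes3 <- mkGenes(c(1000, 1701), c(1500, 2300), c("+", "+"),
        c("up", "down"))
    expect_true("down" %in%
        mcols(selectPhasingGenes(genes3))$gene_id)
    # promoter running off the chromosome start fails
    genes4 <- mkGenes(100, 700, "+", "edge")
    expect_length(selectPhasingGenes(genes4), 0L)
})

test_that("phasing profile averages per-base nucleosome density", {
    genes <- mkGenes(1000, 1600, "+", "g1")
    t1 <- mkTrack(rep("N", 900), start = 700, id = "m1")
    t2 <- mkTrack(rep("A", 900), start = 700, id = "m2")
    tracks <- StateTrackSet(
        c(granges(t1), granges(t2)), c("m1", "m2"),
        list(rep("N", 900), rep("A", 900)))
    prof <- phasingProfile(tracks, genes, flank = 400)
    expect_equal(prof$density[prof$offset == 0], 0.5)
    # offsets with no coverage at all contribute no genes
    expect_true(is.na(prof$density[prof$offset == -400]))
    expect_identical(prof$nGenes[prof$offset == -400], 0L)
    expect_equal(prof$density[prof$offset == -300], 0.5)
    # single-read coverage at offsets covered by m1 only
    t3tracks <- StateTrackSet(
        c(granges(t1), GRanges("chrT", IRanges(995, 1300))),
        c("m1", "m3"), list(rep("N", 900), rep("A", 306)))
    prof3 <- phasingProfile(t3tracks, genes, flank = 400)
    expect_equal(prof3$density[prof3$offset == 350], 1)  # m1 only
    expect_equal(prof3$density[prof3$offset == 100], 0.5)
    expect_true(all(prof3$density >= 0 & prof3$density <= 1,
        na.rm = TRUE))
})

test_that("state vectors have the documented length and orientation", {
    genes <- mkGenes(1000, 1800, "+", "g1")
    lab <- c(rep("A", 301), rep("N", 300))  # A up to TSS, N after
    tr <- mkTrack(lab, start = 700, id = "m1")
    v <- stateVectors(tr, tss = 1000, chrom = "chrT", "+", flank = 300)
    expect_identical(dim(v), c(601L, 1L))
    expect_equal(as.numeric(v[1, 1]), 0)    # upstream edge accessible
    expect_equal(as.numeric(v[601, 1]), 1)  # downstream edge nucleosomal
    # minus-strand orientation flips the vector
    vMinus <- stateVectors(tr, tss = 1000, chrom = "chrT", "-",
        flank = 300)
    expect_equal(vMinus[, 1], rev(v[, 1]))
    # partially covering reads are excluded
    short <- mkTrack(rep("A", 500), start = 800, id = "m2")
    expect_identical(ncol(stateVectors(short, 1000, "chrT", "+", 300)),
        0L)
})

test_that("heterogeneity scores reach the correlation extremes", {
    genes <- mkGenes(1000, 1800, "+", "g1")
    v <- rep(c("A", "N"), length.out = 701)
    mk <- function(labels, ids) StateTrackSet(
        GRanges("chrT", IRanges(rep(650L, length(ids)),
            rep(1350L, length(ids)))), ids, labels)
    identical6 <- mk(replicate(6, v, simplify = FALSE),
        sprintf("m%d", 1:6))
    sc <- heterogeneityScores(identical6, genes, minReads = 6)
    expect_equal(sc$het_score, 1.0)
    expect_identical(sc$n_pairs, 15L)
    # perfectly anti-correlated pair
    vInv <- ifelse(v == "A", "N", "A")
    pair <- mk(list(v, vInv), c("p1", "p2"))
    sc2 <- heterogeneityScores(pair, genes, minReads = 2)
    expect_equal(sc2$het_score, -1.0)
    # genes below the read threshold are omitted
    expect_identical(nrow(heterogeneityScores(pair, genes,
        minReads = 6)), 0L)
})

test_that("constant vectors are skipped, reads without accessible bases excluded", {
    genes <- mkGenes(1000, 1800, "+", "g1")
    v <- rep(c("A", "N"), length.out = 701)
    allN <- rep("N", 701)    # constant AND no accessible base
    mixed <- c(rep("A", 350), rep("X", 351))  # has accessible, varies
    tracks <- StateTrackSet(
        GRanges("chrT", IRanges(rep(650L, 3), rep(1350L, 3))),
        c("m1", "m2", "m3"), list(v, allN, mixed))
    sc <- heterogeneityScores(tracks, genes, minReads = 2)
    # the all-nucleosomal molecule fails the accessible-region filter
    expect_identical(sc$n_reads, 2L)
    expect_identical(sc$n_pairs, 1L)
})

test_that("heterogeneity histogram uses fixed 0.05 bins over [-1, 1]", {
    h <- heterogeneityHistogram(numeric(0))
    expect_identical(nrow(h), 40L)
    expect_true(all(h$count == 0L))
    h2 <- heterogeneityHistogram(c(0.42))
    expect_identical(h2$count[h2$binStart == 0.40], 1L)
    expect_identical(sum(h2$count), 1L)
    h3 <- heterogeneityHistogram(c(-1, 1, 0.999))
    expect_identical(h3$count[1], 1L)
    expect_identical(h3$count[40], 2L)
})

test_that("mirroring a gene to the minus strand leaves results unchanged", {
    set.seed(33)
    flank <- 50L
    n <- 6L
    labs <- replicate(n, sample(c("A", "N", "X"), 2 * flank + 101,
        replace = TRUE, prob = c(.5, .4, .1)), simplify = FALSE)
    tssPlus <- 500L
    plusTracks <- StateTrackSet(
        GRanges("chrT", IRanges(rep(tssPlus - flank - 50L, n),
            rep(tssPlus + flank + 50L, n))), sprintf("m%d", 1:n), labs)
    genePlus <- mkGenes(tssPlus, tssPlus + 300L, "+", "g")
    # mirrored scenario: flip every track around the TSS
    tssMinus <- 2000L
    mirLabs <- lapply(labs, rev)
    minusTracks <- StateTrackSet(
        GRanges("chrT", IRanges(rep(tssMinus - flank - 50L, n),
            rep(tssMinus + flank + 50L, n))), sprintf("m%d", 1:n),
        mirLabs)
    geneMinus <- mkGenes(tssMinus - 300L, tssMinus, "-", "g")
    hetP <- heterogeneityScores(plusTracks, genePlus, flank = flank,
        minReads = 3)
    hetM <- heterogeneityScores(minusTracks, geneMinus, flank = flank,
        minReads = 3)
    expect_equal(hetP$het_score, hetM$het_score)
    profP <- phasingProfile(plusTracks, genePlus, flank = flank)
    profM <- phasingProfile(minusTracks, geneMinus, flank = flank)
    expect_equal(profP$density, profM$density)
})

test_that("heterogeneity decreases with simulated positional jitter", {
    base <- list(seed = 23, genomeLength = 60000L,
        readMethDistribution = "fixed", readMethFixed = 0.15)
    means <- vapply(c(0, 40), function(js) {
        sc <- do.call(SimConfig, c(base, jitterSd = js))
        g <- simulateGenome(sc)
        genes <- g$genes[1:15]
        sim <- simulateNucleiReads(sc, g$genome, genes = genes,
            readsPerGene = 8)
        het <- heterogeneityScores(sim$truth, genes, minReads = 6)
        mean(het$het_score, na.rm = TRUE)
    }, numeric(1))
    expect_gt(means[1], means[2])
})
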