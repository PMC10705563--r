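#' Simulator configuration
#'
#' Builds a \linkS4class{SimConfig} with defaults emulating the
#' statistical structure of M.EcoGII footprinting data: 60\% AT genome,
#' ~1 kb reads, per-read m6A detection fraction lognormal with median
#' 11\% (matching the observed ~11 +/- 6\% spread), 147-bp nucleosome
#' footprints with ~18-bp linkers, promoter NDRs, and 1\% residual
#' methylation inside footprints.
#'
#' @param seed integer RNG seed.
#' @param genomeLength genome size in bp.
#' @param atContent genome mean A+T fraction.
#' @param atBlockSd,blockLength compositional heterogeneity: per-block
#'   SD of the local AT content and the block length in bp.
#' @param readLengthMean,readLengthSd read length distribution.
#' @param readMethDistribution "lognormal" or "fixed".
#' @param readMethMedian,readMethSdlog,readMethFixed,readMethMax per-read
#'   m6A fraction distribution parameters.
#' @param nucleosomeFootprint,linkerMean,linkerSd,ndrLength footprint
#'   geometry in bp.
#' @param nucleosomalFraction window-mode nucleosomal fraction.
#' @param nucleosomeMeth intra-footprint detection fraction.
#' @param jitterSd per-molecule positional jitter SD in bp.
#' @param atBiasModel multiplier per window AT count (length
#'   windowSize + 1), or NULL for no bias.
#' @param polyABiasModel multiplier per poly(A) run length, or NULL.
#' @param qualityConstant simulated average read quality.
#' @param windowSize window size for the AT-bias lookup.
#' @return a \linkS4class{SimConfig}.
#' @export
SimConfig <- function(seed = 1L, genomeLength = 100000L,
        atContent = 0.6, atBlockSd = 0.1, blockLength = 500L,
        readLengthMean = 1000, readLengthSd = 0,
        readMethDistribution = c("lognormal", "fixed"),
        readMethMedian = 0.11, readMethSdlog = 0.5,
        readMethFixed = 0.11, readMethMax = 0.75,
        nucleosomeFootprint = 147L, linkerMean = 18, linkerSd = 5,
        ndrLength = 140L, nucleosomalFraction = 0.7,
        nucleosomeMeth = 0.01, jitterSd = 0, atBiasModel = NULL,
        polyABiasModel = NULL, qualityConstant = 99,
        windowSize = 25L) {
    W <- as.integer(windowSize)
    if (is.null(atBiasModel)) atBiasModel <- rep(1, W + 1L)
    if (is.null(polyABiasModel)) polyABiasModel <- rep(1, 8L)
    new("SimConfig", seed = as.integer(seed),
        genomeLength = as.integer(genomeLength), atContent = atContent,
        atBlockSd = atBlockSd, blockLength = as.integer(blockLength),
        readLengthMean = readLengthMean, readLengthSd = readLengthSd,
        readMethDistribution = match.arg(readMethDistribution),
        readMethMedian = readMethMedian, readMethSdlog = readMethSdlog,
        readMethFixed = readMethFixed, readMethMax = readMethMax,
        nucleosomeFootprint = as.integer(nucleosomeFootprint),
        linkerMean = linkerMean, linkerSd = linkerSd,
        ndrLength = as.integer(ndrLength),
        nucleosomalFraction = nucleosomalFraction,
        nucleosomeMeth = nucleosomeMeth, jitterSd = jitterSd,
        atBiasModel = atBiasModel, polyABiasModel = polyABiasModel,
        qualityConstant = qualityConstant, windowSize = W)
}

#' Linear AT-count detection bias
#'
#' Convenience constructor for an \code{atBiasModel} in which the
#' detection multiplier decreases linearly with the window adenine
#' count, emulating the observed loss of m6A calling efficiency in
#' AT-rich windows: multiplier(N) = 1 + slopePerN * (N - refN), floored
#' at \code{floorAt}.
#'
#' @param windowSize window size (lookup covers AT counts 0..windowSize).
#' @param slopePerN change in multiplier per unit AT count (negative
#'   for a bias against AT-rich windows).
#' @param refN AT count at which the multiplier is 1 (default 16, the
#'   count at which real windows behave as expected).
#' @param floorAt lower bound on the multiplier.
#' @return numeric vector of length windowSize + 1.
#' @export
linearATBias <- function(windowSize = 25L, slopePerN = -0.02,
        refN = 16L, floorAt = 0.05) {
    pmax(1 + slopePerN * ((0:windowSize) - refN), floorAt)
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: seed %d, %d-bp genome at %.0f%% AT, ",
        "%s read methylation, %d-bp footprints\n"), object@seed,
        object@genomeLength, 100 * object@atContent,
        object@readMethDistribution, object@nucleosomeFootprint))
})

#' Simulate a reference genome with a gene annotation
#'
#' Random sequence whose local AT content varies block-by-block around
#' the configured mean (emulating the compositional heterogeneity of
#' real genomes, which is what populates the extreme window AT counts
#' the calibration covers), plus non-overlapping
#' genes (>= 200 bp) separated by intergenic gaps (>= 200 bp) so that
#' every gene qualifies for TSS-anchored analyses. Gene strands
#' alternate; the TSS is the 5' end of the gene span.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed (default the config seed).
#' @return list with \code{genome} (a named
#'   \link[Biostrings]{DNAStringSet}, one chromosome "chrSim") and
#'   \code{genes} (GRanges with mcols \code{gene_id}).
#' @export
simulateGenome <- function(config, seed = config@seed) {
    set.seed(seed)
    L <- config@genomeLength
    nBlocks <- ceiling(L / config@blockLength)
    atLocal <- pmin(pmax(stats::rnorm(nBlocks, config@atContent,
        config@atBlockSd), 0.05), 0.95)
    at <- rep(atLocal, each = config@blockLength)[seq_len(L)]
    if (config@atBlockSd == 0) at <- rep(config@atContent, L)
    isAT <- stats::runif(L) < at
    bases <- ifelse(isAT,
        sample(c("A", "T"), L, replace = TRUE),
        sample(c("C", "G"), L, replace = TRUE))
    genome <- DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chrSim"
    starts <- integer(0)
    ends <- integer(0)
    pos <- 1L
    repeat {
        gap <- sample(250:400, 1L)
        glen <- sample(500:900, 1L)
        if (pos + gap + glen + 250L > L) break
        starts <- c(starts, pos + gap)
        ends <- c(ends, pos + gap + glen - 1L)
        pos <- pos + gap + glen
    }
    n <- length(starts)
    strands <- rep(c("+", "-"), length.out = n)
    genes <- GRanges("chrSim", IRanges(starts, ends), strand = strands)
    mcols(genes)$gene_id <- sprintf("gene%04d", seq_len(n))
    list(genome = genome, genes = genes)
}

# Genome-wide precomputation for the detection model: window AT count
# centered at each position (clipped at the edges) and same-strand
# poly(A) run length at each adenine.
.detectionContext <- function(genome, config) {
    lapply(genome, function(chromSeq) {
        codes <- as.integer(chromSeq)
        at <- .isAT(codes)
        L <- length(at)
        W <- config@windowSize
        half <- W %/% 2L
        cs <- c(0, cumsum(at))
        lo <- pmax(seq_len(L) - half, 1L)
        hi <- pmin(seq_len(L) + half, L)
        list(at = at,
            atc = as.integer(cs[hi + 1L] - cs[lo]),
            run = .polyARunLengths(chromSeq))
    })
}

.drawReadFractions <- function(config, n) {
    f <- switch(config@readMethDistribution,
        lognormal = exp(stats::rnorm(n, log(config@readMethMedian),
            config@readMethSdlog)),
        fixed = rep(config@readMethFixed, n))
    pmin(f, config@readMethMax)
}

# Per-adenine detection probability for accessible DNA at positions idx
# (genome coordinates) given the per-read fraction f.
.detectionProb <- function(ctx, idx, f, config) {
    mult <- config@atBiasModel[ctx$atc[idx] + 1L] *
        config@polyABiasModel[pmin(ctx$run[idx],
            length(config@polyABiasModel))]
    pmin(f * mult, 1)
}

#' Simulate a fully-accessible (gDNA) control read set
#'
#' Every adenine is a detection candidate. Each read draws its overall
#' detection fraction from the configured per-read distribution; the
#' per-adenine detection probability is that fraction times the AT-count
#' and poly(A) bias multipliers, followed by Bernoulli sampling.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genome named \link[Biostrings]{DNAStringSet} (e.g. from
#'   \code{\link{simulateGenome}}).
#' @param nReads number of reads.
#' @param seed RNG seed (default derived from the config seed).
#' @return a \linkS4class{MethylReadSet}.
#' @export
simulateGdnaReads <- function(config, genome, nReads,
        seed = .childSeed(config@seed, 1L)) {
    set.seed(seed)
    ctx <- .detectionContext(genome, config)[[1]]
    chrom <- names(genome)[1]
    L <- length(genome[[1]])
    lens <- pmax(config@windowSize + 1,
        round(stats::rnorm(nReads, config@readLengthMean,
            config@readLengthSd)))
    lens <- pmin(lens, L)
    starts <- 1L + as.integer(floor(stats::runif(nReads) * (L - lens + 1)))
    f <- .drawReadFractions(config, nReads)
    m6aPos <- vector("list", nReads)
    m6aStr <- vector("list", nReads)
    codesAll <- as.integer(genome[[1]])
    for (i in seq_len(nReads)) {
        span <- starts[i]:(starts[i] + lens[i] - 1L)
        aIdx <- span[ctx$at[span]]
        hit <- stats::runif(length(aIdx)) <
            .detectionProb(ctx, aIdx, f[i], config)
        m6aPos[[i]] <- aIdx[hit]
        m6aStr[[i]] <- ifelse(codesAll[aIdx[hit]] == .CODE_A, "+", "-")
    }
    MethylReadSet(sprintf("gdna%06d", seq_len(nReads)),
        rep(chrom, nReads), starts, starts + lens - 1L,
        rep(config@qualityConstant, nReads), m6aPos, m6aStr, genome)
}

#' Simulate fully-protected reads
#'
#' Reads whose entire span is protected (truth all nucleosomal), with
#' per-adenine detection at the intra-footprint rate. Serves as the
#' truth set for estimating the accessible-call false-positive rate,
#' which a fully-accessible control cannot provide.
#'
#' @inheritParams simulateGdnaReads
#' @return list with \code{reads} (\linkS4class{MethylReadSet}) and
#'   \code{truth} (\linkS4class{StateTrackSet}, all nucleosomal).
#' @export
simulateProtectedReads <- function(config, genome, nReads,
        seed = .childSeed(config@seed, 2L)) {
    set.seed(seed)
    ctx <- .detectionContext(genome, config)[[1]]
    chrom <- names(genome)[1]
    L <- length(genome[[1]])
    lens <- pmin(pmax(config@windowSize + 1,
        round(stats::rnorm(nReads, config@readLengthMean,
            config@readLengthSd))), L)
    starts <- 1L + as.integer(floor(stats::runif(nReads) * (L - lens + 1)))
    codesAll <- as.integer(genome[[1]])
    m6aPos <- vector("list", nReads)
    m6aStr <- vector("list", nReads)
    for (i in seq_len(nReads)) {
        span <- starts[i]:(starts[i] + lens[i] - 1L)
        aIdx <- span[ctx$at[span]]
        hit <- stats::runif(length(aIdx)) < config@nucleosomeMeth
        m6aPos[[i]] <- aIdx[hit]
        m6aStr[[i]] <- ifelse(codesAll[aIdx[hit]] == .CODE_A, "+", "-")
    }
    reads <- MethylReadSet(sprintf("prot%06d", seq_len(nReads)),
        rep(chrom, nReads), starts, starts + lens - 1L,
        rep(config@qualityConstant, nReads), m6aPos, m6aStr, genome)
    truth <- StateTrackSet(granges(reads), moleculeId(reads),
        lapply(lens, function(l) S4Vectors::Rle("N", l)))
    list(reads = reads, truth = truth)
}

# Genome-wide chromatin layout: an NDR at every promoter (strand-
# oriented, immediately upstream of the TSS) and footprint/linker
# arrays tiling the regions between NDRs. The map is a property of the
# locus, so every molecule covering a promoter sees its NDR; per-
# molecule heterogeneity is added later as a positional shift.
.chromatinLayout <- function(genes, L, config) {
    fp <- config@nucleosomeFootprint
    tss <- ifelse(as.character(strand(genes)) == "-", end(genes),
        start(genes))
    minus <- as.character(strand(genes)) == "-"
    ndrS <- ifelse(minus, tss - 4L, tss - config@ndrLength - 5L)
    ndrE <- ifelse(minus, tss + config@ndrLength + 5L, tss + 4L)
    ndr <- IRanges::reduce(IRanges(pmax(ndrS, 1L), pmin(ndrE, L)))
    gapS <- c(1L, end(ndr) + 1L)
    gapE <- c(start(ndr) - 1L, L)
    drawLinker <- function() pmax(5, round(stats::rnorm(1,
        config@linkerMean, config@linkerSd)))
    starts <- integer(0)
    for (k in seq_along(gapS)) {
        # arrays phase off both flanking NDRs and meet in the middle
        mid <- (gapS[k] + gapE[k]) / 2
        p <- gapS[k]
        leftEnd <- gapS[k] - 1L
        while (p + fp - 1L <= gapE[k] && p <= mid) {
            starts <- c(starts, p)
            leftEnd <- p + fp - 1L
            p <- p + fp + drawLinker()
        }
        q <- gapE[k]
        while (q - fp + 1L > leftEnd) {
            starts <- c(starts, q - fp + 1L)
            q <- q - fp - drawLinker()
        }
    }
    sort(starts)
}

# Truth label vector ("A"/"N") over a read span from footprint starts.
.truthFromStarts <- function(fpStarts, fp, readStart, readEnd) {
    lab <- rep("A", readEnd - readStart + 1L)
    for (s in fpStarts) {
        a <- max(s, readStart)
        b <- min(s + fp - 1L, readEnd)
        if (a <= b) lab[(a - readStart + 1L):(b - readStart + 1L)] <- "N"
    }
    lab
}

#' Simulate chromatinised (nuclei) reads with ground truth
#'
#' Lays nucleosome arrays on the genome and samples reads whose
#' accessible positions follow the gDNA detection model while
#' positions inside footprints are detected at the intra-footprint rate
#' (default 1\%). The per-read overall m6A fraction f is drawn from the
#' configured distribution and the accessible detection probability is
#' solved from the mass balance f = q * nucleosomeMeth + (1 - q) * pAcc,
#' where q is the read's nucleosomal adenine fraction.
#'
#' With a gene annotation, one genome-wide chromatin map is laid down
#' (an NDR immediately upstream of every TSS, strand-oriented, and
#' phased footprint/linker arrays tiling the DNA between NDRs); each
#' molecule sees that map shifted by a normal positional jitter (SD
#' \code{jitterSd}), creating cell-to-cell heterogeneity, and reads are
#' centered on their gene's TSS. Without genes, each read gets an
#' independent footprint/linker tiling (arrays of ~8 nucleosomes
#' separated by NDRs) with a random phase.
#'
#' @inheritParams simulateGdnaReads
#' @param genes optional GRanges gene annotation (from
#'   \code{\link{simulateGenome}}); when supplied, reads are anchored at
#'   gene TSSs.
#' @param readsPerGene number of molecules per gene (used when
#'   \code{genes} is supplied; \code{nReads} is ignored then).
#' @return list with \code{reads} (\linkS4class{MethylReadSet}) and
#'   \code{truth} (\linkS4class{StateTrackSet}).
#' @export
simulateNucleiReads <- function(config, genome, nReads = 1000L,
        genes = NULL, readsPerGene = 20L,
        seed = .childSeed(config@seed, 3L)) {
    set.seed(seed)
    ctx <- .detectionContext(genome, config)[[1]]
    chrom <- names(genome)[1]
    L <- length(genome[[1]])
    fp <- config@nucleosomeFootprint
    codesAll <- as.integer(genome[[1]])
    if (is.null(genes)) {
        lens <- pmin(pmax(config@windowSize + 1,
            round(stats::rnorm(nReads, config@readLengthMean,
                config@readLengthSd))), L)
        starts <- 1L + as.integer(floor(stats::runif(nReads) *
            (L - lens + 1)))
        # arrays of ~8 nucleosomes separated by NDRs, emulating yeast
        # promoter spacing; random phase per molecule
        nucsPerArray <- 8L
        layout <- lapply(seq_len(nReads), function(i) {
            period <- config@ndrLength +
                nucsPerArray * (fp + config@linkerMean)
            phase <- as.integer(floor(stats::runif(1) * period))
            first <- starts[i] - phase - period
            fs <- integer(0)
            p <- first
            repeat {
                p <- p + config@ndrLength
                for (u in seq_len(nucsPerArray)) {
                    fs <- c(fs, p)
                    p <- p + fp + pmax(5, round(stats::rnorm(1,
                        config@linkerMean, config@linkerSd)))
                }
                if (p > starts[i] + lens[i] - 1L) break
            }
            fs
        })
        ids <- sprintf("nuc%06d", seq_len(nReads))
    } else {
        tssAll <- ifelse(as.character(strand(genes)) == "-", end(genes),
            start(genes))
        n <- length(genes) * readsPerGene
        geneIdx <- rep(seq_along(genes), each = readsPerGene)
        lens <- pmin(pmax(config@windowSize + 1,
            round(stats::rnorm(n, config@readLengthMean,
                config@readLengthSd))), L)
        centerOff <- as.integer(round(stats::runif(n, -30, 30)))
        starts <- pmax(1L, pmin(L - lens + 1L,
            tssAll[geneIdx] - lens %/% 2L + centerOff))
        # one genome-wide base map, shifted per molecule
        baseStarts <- .chromatinLayout(genes, L, config)
        jit <- as.integer(round(stats::rnorm(n, 0, config@jitterSd)))
        layout <- lapply(seq_len(n), function(i) baseStarts + jit[i])
        ids <- sprintf("%s_mol%03d", mcols(genes)$gene_id[geneIdx],
            seq_len(n) %% readsPerGene + 1L)
        ids <- make.unique(ids)
        nReads <- n
    }
    f <- .drawReadFractions(config, nReads)
    m6aPos <- vector("list", nReads)
    m6aStr <- vector("list", nReads)
    truthLab <- vector("list", nReads)
    for (i in seq_len(nReads)) {
        readEnd <- starts[i] + lens[i] - 1L
        lab <- .truthFromStarts(layout[[i]], fp, starts[i], readEnd)
        truthLab[[i]] <- lab
        span <- starts[i]:readEnd
        isA <- ctx$at[span]
        aIdx <- span[isA]
        nucA <- lab[isA] == "N"
        q <- mean(nucA)
        pAcc <- if (q < 1) (f[i] - q * config@nucleosomeMeth) / (1 - q)
            else 0
        pAcc <- min(max(pAcc, 0), 1)
        p <- ifelse(nucA, config@nucleosomeMeth,
            .detectionProb(ctx, aIdx, pAcc, config))
        hit <- stats::runif(length(aIdx)) < p
        m6aPos[[i]] <- aIdx[hit]
        m6aStr[[i]] <- ifelse(codesAll[aIdx[hit]] == .CODE_A, "+", "-")
    }
    reads <- MethylReadSet(ids, rep(chrom, nReads), starts,
        starts + lens - 1L, rep(config@qualityConstant, nReads),
        m6aPos, m6aStr, genome)
    truth <- StateTrackSet(granges(reads), moleculeId(reads), truthLab)
    list(reads = reads, truth = truth)
}

#' Write simulated genes as a 6-column BED
#'
#' Gene spans with name = gene id and strand; the TSS is the 5' end.
#'
#' @param genes GRanges with mcols \code{gene_id}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneBed <- function(genes, path) {
    df <- data.frame(chrom = as.character(seqnames(genes)),
        start = start(genes) - 1L, end = end(genes),
        name = mcols(genes)$gene_id, score = 0L,
        strand = as.character(strand(genes)))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' Read a 6-column gene BED
#'
#' @param path BED path (chrom, start, end, name, score, strand).
#' @return GRanges with mcols \code{gene_id}.
#' @export
readGeneBed <- function(path) {
    df <- utils::read.delim(path, header = FALSE,
        col.names = c("chrom", "start", "end", "name", "score",
            "strand"))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
        strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
    mcols(gr)$gene_id <- as.character(df$name)
    gr
}
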