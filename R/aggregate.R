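# Population-level aggregation: TSS-anchored nucleosome density and the
# per-gene nucleosome-position heterogeneity score.

.tssOf <- function(genes) {
    ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Select genes for TSS-anchored analyses
#'
#' Retains genes that overlap no other gene, are at least
#' \code{minGeneLength} long, and whose promoter (the
#' \code{minPromoter} bp immediately upstream of the TSS,
#' strand-oriented) lies inside the chromosome and overlaps no other
#' gene.
#'
#' @param genes GRanges with mcols \code{gene_id} and meaningful
#'   strands.
#' @param minGeneLength minimum gene length in bp (default 200).
#' @param minPromoter minimum clear promoter length in bp (default 200).
#' @param chromLengths optional named vector of chromosome lengths used
#'   to reject promoters running off the ends.
#' @return the retained GRanges subset.
#' @export
selectPhasingGenes <- function(genes, minGeneLength = 200L,
        minPromoter = 200L, chromLengths = NULL) {
    if (!length(genes)) return(genes)
    selfOv <- GenomicRanges::countOverlaps(genes, genes,
        ignore.strand = TRUE)
    tss <- .tssOf(genes)
    minus <- as.character(strand(genes)) == "-"
    promStart <- ifelse(minus, tss + 1L, tss - minPromoter)
    promEnd <- ifelse(minus, tss + minPromoter, tss - 1L)
    inBounds <- promStart >= 1L
    if (!is.null(chromLengths))
        inBounds <- inBounds &
            promEnd <= chromLengths[as.character(seqnames(genes))]
    prom <- GRanges(seqnames(genes),
        IRanges(pmax(promStart, 1L), pmax(promEnd, 1L)))
    promClear <- GenomicRanges::countOverlaps(prom, genes,
        ignore.strand = TRUE) == 0L
    genes[selfOv == 1L & width(genes) >= minGeneLength & inBounds &
        promClear]
}

# Decode one track's labels over the genome interval [lo, hi]
# (requires the track to cover it fully) as a character vector.
.trackSlice <- function(tracks, i, lo, hi) {
    st <- start(granges(tracks))[i]
    as.character(tracks@labels[[i]][(lo - st + 1L):(hi - st + 1L)])
}

#' TSS-anchored nucleosome density profile
#'
#' For each gene and strand-oriented offset in [-flank, +flank] around
#' the TSS, the nucleosome density is the fraction of reads covering
#' that base pair in which it is labelled nucleosomal. The profile is
#' the unweighted mean over genes with coverage at that offset. On
#' phased chromatin it oscillates with the nucleosome repeat length,
#' with a minimum in the promoter NDR.
#'
#' @param tracks a \linkS4class{StateTrackSet} of resolved calls.
#' @param genes GRanges of selected genes (see
#'   \code{\link{selectPhasingGenes}}).
#' @param flank half-width of the profile in bp (default 400).
#' @return data.frame with columns \code{offset} (bp, negative =
#'   upstream), \code{density} in [0, 1], and \code{nGenes}.
#' @export
phasingProfile <- function(tracks, genes, flank = 400L) {
    flank <- as.integer(flank)
    width <- 2L * flank + 1L
    gr <- granges(tracks)
    tss <- .tssOf(genes)
    win <- GRanges(seqnames(genes),
        IRanges(tss - flank, tss + flank))
    ov <- GenomicRanges::findOverlaps(win, gr, ignore.strand = TRUE)
    sumD <- numeric(width)
    nG <- integer(width)
    for (g in seq_along(genes)) {
        idx <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == g]
        if (!length(idx)) next
        cov <- nuc <- numeric(width)
        lo <- tss[g] - flank
        hi <- tss[g] + flank
        for (i in idx) {
            a <- max(lo, start(gr)[i])
            b <- min(hi, end(gr)[i])
            if (a > b) next
            lab <- .trackSlice(tracks, i, a, b)
            at <- (a - lo + 1L):(b - lo + 1L)
            cov[at] <- cov[at] + 1
            nuc[at] <- nuc[at] + (lab == "N")
        }
        dens <- ifelse(cov > 0, nuc / cov, NA_real_)
        if (as.character(strand(genes))[g] == "-") dens <- rev(dens)
        has <- !is.na(dens)
        sumD[has] <- sumD[has] + dens[has]
        nG[has] <- nG[has] + 1L
    }
    data.frame(offset = (-flank):flank,
        density = ifelse(nG > 0, sumD / nG, NA_real_), nGenes = nG)
}

#' Single-molecule chromatin state vectors around a TSS
#'
#' Extracts, for each track fully covering the TSS window, the
#' strand-oriented state vector of length 2 * flank + 1 encoded as
#' accessible = 0, ambiguous = 0.5, nucleosomal = 1.
#'
#' @param tracks a \linkS4class{StateTrackSet}.
#' @param tss TSS position (1-based).
#' @param chrom chromosome name.
#' @param geneStrand "+" or "-".
#' @param flank half-width (default 300, a 601-bp vector).
#' @return numeric matrix, one column per qualifying molecule (named by
#'   molecule id); 0 columns when no track fully covers the window.
#' @export
stateVectors <- function(tracks, tss, chrom, geneStrand = "+",
        flank = 300L) {
    gr <- granges(tracks)
    lo <- tss - flank
    hi <- tss + flank
    sel <- which(as.character(seqnames(gr)) == chrom &
        start(gr) <= lo & end(gr) >= hi)
    enc <- c(A = 0, X = 0.5, N = 1)
    mat <- matrix(numeric(0), nrow = 2L * flank + 1L, ncol = 0L)
    if (length(sel)) {
        cols <- lapply(sel, function(i) {
            v <- enc[.trackSlice(tracks, i, lo, hi)]
            if (geneStrand == "-") v <- rev(v)
            unname(v)
        })
        mat <- do.call(cbind, cols)
        colnames(mat) <- moleculeId(tracks)[sel]
    }
    mat
}

#' Per-gene nucleosome-position heterogeneity scores
#'
#' For each gene with more than \code{minReads - 1} reads that fully
#' cover the TSS +/- flank window and contain at least one accessible
#' base inside it (excluding molecules with too few m6A to be
#' informative), every unordered pair of state vectors (accessible = 0,
#' ambiguous = 0.5, nucleosomal = 1) is compared by product-moment
#' correlation; the gene's heterogeneity score is the mean over pairs.
#' Pairs in which either vector is constant (correlation undefined) are
#' skipped and counted. A score near 1 means nucleosomes occupy the
#' same positions on every molecule; low or negative scores mean
#' cell-to-cell variability in nucleosome positioning.
#'
#' @param tracks a \linkS4class{StateTrackSet}.
#' @param genes GRanges of genes (mcols \code{gene_id}).
#' @param flank half-width of the window (default 300).
#' @param minReads minimum qualifying reads per gene (default 6).
#' @return data.frame with columns \code{gene_id}, \code{n_reads},
#'   \code{n_pairs}, \code{n_skipped_pairs}, \code{het_score}; genes
#'   with too few qualifying reads are omitted.
#' @export
heterogeneityScores <- function(tracks, genes, flank = 300L,
        minReads = 6L) {
    rows <- vector("list", length(genes))
    tss <- .tssOf(genes)
    for (g in seq_along(genes)) {
        mat <- stateVectors(tracks, tss[g],
            as.character(seqnames(genes))[g],
            as.character(strand(genes))[g], flank)
        if (!ncol(mat)) next
        hasAcc <- colSums(mat == 0) > 0
        mat <- mat[, hasAcc, drop = FALSE]
        nr <- ncol(mat)
        if (nr < minReads) next
        sds <- apply(mat, 2L, stats::sd)
        cm <- suppressWarnings(stats::cor(mat))
        ut <- upper.tri(cm)
        nonconst <- outer(sds > 0, sds > 0, `&`)
        vals <- cm[ut & nonconst]
        nSkip <- sum(ut) - length(vals)
        rows[[g]] <- data.frame(gene_id = mcols(genes)$gene_id[g],
            n_reads = nr, n_pairs = length(vals),
            n_skipped_pairs = nSkip,
            het_score = if (length(vals)) mean(vals) else NA_real_)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out))
        out <- data.frame(gene_id = character(0), n_reads = integer(0),
            n_pairs = integer(0), n_skipped_pairs = integer(0),
            het_score = numeric(0))
    out
}

#' Histogram of heterogeneity scores
#'
#' Fixed bins of width \code{binWidth} over [-1, 1]; the final bin is
#' closed on the right so a score of exactly 1 is counted.
#'
#' @param scores numeric vector of per-gene heterogeneity scores (or
#'   the data.frame from \code{\link{heterogeneityScores}}).
#' @param binWidth bin width (default 0.05).
#' @return data.frame with columns \code{binStart}, \code{binEnd},
#'   \code{count}.
#' @export
heterogeneityHistogram <- function(scores, binWidth = 0.05) {
    if (is.data.frame(scores)) scores <- scores$het_score
    scores <- scores[!is.na(scores)]
    breaks <- seq(-1, 1, by = binWidth)
    idx <- findInterval(scores, breaks, rightmost.closed = TRUE)
    data.frame(binStart = round(breaks[-length(breaks)], 10),
        binEnd = round(breaks[-1], 10),
        count = tabulate(idx, nbins = length(breaks) - 1L))
}
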